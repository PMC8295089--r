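#' Molecular topology for multiscale entropy analysis
#'
#' An `mcc_topology` describes the atoms, bonds and molecule membership of a
#' simulation box, plus the two pieces of structure the multiscale entropy
#' decomposition needs: the united-atom (UA) partition -- each non-hydrogen
#' atom together with all of its bonded hydrogens forms one rigid body -- and
#' the flexible heavy-atom dihedrals used for conformational entropy.
#'
#' @param masses numeric vector of atomic masses (amu), one per atom.
#' @param elements character vector of element symbols, one per atom.
#' @param bonds two-column integer matrix of 1-based atom indices (may have
#'   zero rows for an unbonded system of point particles).
#' @param molecules list of integer vectors, each the atom indices of one
#'   molecule. Every atom must appear in exactly one molecule.
#' @param species character vector, one per molecule: `"solute"`, `"water"`,
#'   `"octanol"` or `"other"`.
#' @param sigma numeric vector of molecular symmetry numbers (>= 1), one per
#'   molecule. Water is conventionally 2; octanol and typical solutes 1.
#' @param flexible_dihedrals optional list (one element per molecule) of
#'   4-column integer matrices of heavy-atom dihedrals. When `NULL`, dihedrals
#'   are auto-detected: one per heavy-atom single bond that is not in a ring
#'   and whose ends each have at least two heavy neighbours.
#'
#' @return An object of class `mcc_topology` with components `masses`,
#'   `elements`, `bonds`, `molecules`, `species`, `sigma`, `united_atoms`
#'   (per molecule, a list of atom-index vectors, first index the heavy atom)
#'   and `flexible_dihedrals`.
#' @export
mcc_topology <- function(masses, elements, bonds, molecules, species, sigma,
                         flexible_dihedrals = NULL) {
  n_atoms <- length(masses)
  stopifnot(length(elements) == n_atoms)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (any(masses <= 0)) stop("atomic masses must be positive")
  if (nrow(bonds) && (any(bonds < 1L) || any(bonds > n_atoms)))
    stop("bond indices out of range")

  molecules <- lapply(molecules, as.integer)
  memb <- unlist(molecules)
  if (length(memb) != n_atoms || anyDuplicated(memb) || !setequal(memb, seq_len(n_atoms)))
    stop("every atom must belong to exactly one molecule")
  n_mol <- length(molecules)
  species <- match.arg(species, c("solute", "water", "octanol", "other"),
                       several.ok = TRUE)
  if (length(species) == 1L) species <- rep(species, n_mol)
  if (length(sigma) == 1L) sigma <- rep(sigma, n_mol)
  stopifnot(length(species) == n_mol, length(sigma) == n_mol)
  if (any(sigma < 1)) stop("symmetry numbers must be >= 1")

  mol_of_atom <- integer(n_atoms)
  for (m in seq_len(n_mol)) mol_of_atom[molecules[[m]]] <- m
  if (nrow(bonds) && any(mol_of_atom[bonds[, 1]] != mol_of_atom[bonds[, 2]]))
    stop("bonds must not cross molecule boundaries")

  is_h <- elements == "H"
  adj <- .adjacency(n_atoms, bonds)

  ## hydrogens attach to their single bonded heavy atom
  for (a in which(is_h)) {
    heavies <- adj[[a]][!is_h[adj[[a]]]]
    if (length(heavies) != 1L)
      stop(sprintf("topology error: hydrogen atom %d bonded to %d heavy atoms",
                   a, length(heavies)))
  }

  united_atoms <- lapply(seq_len(n_mol), function(m) {
    atoms <- molecules[[m]]
    heavies <- atoms[!is_h[atoms]]
    if (!length(heavies))
      stop(sprintf("molecule %d has no heavy atom", m))
    lapply(heavies, function(h) c(h, adj[[h]][is_h[adj[[h]]]]))
  })

  if (is.null(flexible_dihedrals)) {
    flexible_dihedrals <- lapply(seq_len(n_mol), function(m)
      .auto_dihedrals(molecules[[m]], adj, is_h))
  } else {
    stopifnot(length(flexible_dihedrals) == n_mol)
    flexible_dihedrals <- lapply(seq_len(n_mol), function(m) {
      d <- flexible_dihedrals[[m]]
      if (is.null(d) || !length(d)) return(matrix(integer(0), ncol = 4))
      d <- matrix(as.integer(d), ncol = 4)
      if (!all(d %in% molecules[[m]]))
        stop(sprintf("dihedral atoms outside molecule %d", m))
      d
    })
  }

  structure(list(masses = masses, elements = elements, bonds = bonds,
                 molecules = molecules, species = species, sigma = sigma,
                 mol_of_atom = mol_of_atom, adjacency = adj,
                 united_atoms = united_atoms,
                 flexible_dihedrals = flexible_dihedrals),
            class = "mcc_topology")
}

.adjacency <- function(n_atoms, bonds) {
  adj <- vector("list", n_atoms)
  for (i in seq_len(n_atoms)) adj[[i]] <- integer(0)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  lapply(adj, function(x) sort(unique(x)))
}

## b--c is a ring bond iff c is still reachable from b without traversing it
.bond_in_ring <- function(b, c, adj) {
  seen <- b
  queue <- setdiff(adj[[b]], c)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == c) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    queue <- c(queue, setdiff(adj[[v]], seen))
  }
  FALSE
}

## One dihedral per rotatable heavy-atom bond: skip ring bonds and bonds to
## terminal heavy atoms; flanking atoms are the lowest-index heavy neighbours.
.auto_dihedrals <- function(atoms, adj, is_h) {
  heavies <- atoms[!is_h[atoms]]
  hadj <- lapply(seq_along(is_h), function(a) adj[[a]][!is_h[adj[[a]]]])
  out <- matrix(integer(0), ncol = 4)
  for (b in heavies) for (cc in hadj[[b]]) {
    if (cc <= b) next
    nb <- setdiff(hadj[[b]], cc)
    nc <- setdiff(hadj[[cc]], b)
    if (!length(nb) || !length(nc)) next      # terminal heavy atom
    if (.bond_in_ring(b, cc, adj)) next
    out <- rbind(out, c(min(nb), b, cc, min(nc)))
  }
  out
}

#' @export
print.mcc_topology <- function(x, ...) {
  cat(sprintf("mcc_topology: %d atoms, %d bonds, %d molecules\n",
              length(x$masses), nrow(x$bonds), length(x$molecules)))
  tab <- table(x$species)
  cat("  species:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  nua <- vapply(x$united_atoms, length, 0L)
  ndi <- vapply(x$flexible_dihedrals, nrow, 0L)
  cat(sprintf("  united atoms per molecule: %s\n",
              paste(utils::head(nua, 10), collapse = " ")))
  cat(sprintf("  flexible dihedrals per molecule: %s\n",
              paste(utils::head(ndi, 10), collapse = " ")))
  invisible(x)
}

#' Relabel the species and symmetry number of a molecule
#'
#' Useful after reading an AMBER prmtop, where only water can be recognised
#' automatically.
#'
#' @param topology an [mcc_topology()]
#' @param molecule 1-based molecule index
#' @param species one of `"solute"`, `"water"`, `"octanol"`, `"other"`
#' @param sigma symmetry number (>= 1); default keeps the current value
#' @return the modified topology
#' @export
topology_set_species <- function(topology, molecule, species, sigma = NULL) {
  stopifnot(inherits(topology, "mcc_topology"))
  species <- match.arg(species, c("solute", "water", "octanol", "other"))
  topology$species[molecule] <- species
  if (!is.null(sigma)) {
    if (sigma < 1) stop("symmetry numbers must be >= 1")
    topology$sigma[molecule] <- sigma
  }
  topology
}

#' Read a molecular topology from file
#'
#' Two dialects are supported: the package's own YAML fixture dialect and a
#' minimal subset of the AMBER prmtop format (masses, atom names, bonds;
#' molecules are derived as bonded connected components, water is recognised
#' by composition and assigned symmetry number 2).
#'
#' @param path path to the topology file
#' @param format `"yaml"` or `"prmtop"`
#' @return an [mcc_topology()]
#' @export
read_topology <- function(path, format = c("yaml", "prmtop")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("topology file not found: ", path)
  switch(format,
         yaml = .read_topology_yaml(path),
         prmtop = .read_topology_prmtop(path))
}

.read_topology_yaml <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed topology YAML: ",
                                           conditionMessage(e)))
  for (field in c("atoms", "molecules"))
    if (is.null(doc[[field]]))
      stop("malformed topology: missing '", field, "' block")
  masses <- vapply(doc$atoms, function(a) {
    if (is.null(a$mass)) stop("malformed topology: atom record without mass")
    as.numeric(a$mass)
  }, 0)
  elements <- vapply(doc$atoms, function(a) {
    if (is.null(a$element)) stop("malformed topology: atom record without element")
    as.character(a$element)
  }, "")
  bonds <- if (is.null(doc$bonds) || !length(doc$bonds)) {
    matrix(integer(0), ncol = 2)
  } else {
    do.call(rbind, lapply(doc$bonds, function(b) as.integer(b[1:2])))
  }
  molecules <- lapply(doc$molecules, function(m) {
    if (is.null(m$atoms)) stop("malformed topology: molecule record without atoms")
    as.integer(m$atoms)
  })
  species <- vapply(doc$molecules, function(m)
    if (is.null(m$species)) "other" else as.character(m$species), "")
  sigma <- vapply(doc$molecules, function(m)
    if (is.null(m$sigma)) 1 else as.numeric(m$sigma), 0)
  fd <- lapply(doc$molecules, function(m) {
    if (is.null(m$flexible_dihedrals)) return(NULL)
    do.call(rbind, lapply(m$flexible_dihedrals, function(d) as.integer(d[1:4])))
  })
  explicit <- !vapply(fd, is.null, TRUE)
  top <- mcc_topology(masses, elements, bonds, molecules, species, sigma)
  if (any(explicit)) {
    auto <- top$flexible_dihedrals
    for (m in which(explicit)) auto[[m]] <- {
      d <- matrix(as.integer(fd[[m]]), ncol = 4)
      if (!all(d %in% molecules[[m]]))
        stop(sprintf("dihedral atoms outside molecule %d", m))
      d
    }
    top$flexible_dihedrals <- auto
  }
  top
}

#' Write a topology in the YAML fixture dialect
#' @param topology an [mcc_topology()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "mcc_topology"))
  doc <- list(
    atoms = lapply(seq_along(topology$masses), function(i)
      list(element = topology$elements[i], mass = topology$masses[i])),
    bonds = if (nrow(topology$bonds))
      lapply(seq_len(nrow(topology$bonds)), function(k)
        as.integer(topology$bonds[k, ])) else list(),
    molecules = lapply(seq_along(topology$molecules), function(m) {
      rec <- list(species = topology$species[m],
                  sigma = topology$sigma[m],
                  atoms = as.integer(topology$molecules[[m]]))
      d <- topology$flexible_dihedrals[[m]]
      if (nrow(d))
        rec$flexible_dihedrals <- lapply(seq_len(nrow(d)), function(k)
          as.integer(d[k, ]))
      rec
    }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

## ---- minimal AMBER prmtop subset -------------------------------------------

.prmtop_sections <- function(lines) {
  flags <- grep("^%FLAG", lines)
  out <- list()
  for (i in seq_along(flags)) {
    name <- sub("^%FLAG\\s+", "", lines[flags[i]])
    name <- trimws(name)
    end <- if (i < length(flags)) flags[i + 1] - 1 else length(lines)
    body <- lines[(flags[i] + 1):end]
    body <- body[!grepl("^%", body)]
    out[[name]] <- body
  }
  out
}

.read_topology_prmtop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- .prmtop_sections(lines)
  for (need in c("POINTERS", "MASS"))
    if (is.null(sec[[need]]))
      stop("malformed prmtop: missing %FLAG ", need)
  ptr <- as.integer(unlist(strsplit(trimws(paste(sec$POINTERS, collapse = " ")),
                                    "\\s+")))
  n_atoms <- ptr[1]
  masses <- as.numeric(unlist(strsplit(trimws(paste(sec$MASS, collapse = " ")),
                                       "\\s+")))
  if (length(masses) != n_atoms)
    stop("malformed prmtop: MASS has ", length(masses),
         " entries for ", n_atoms, " atoms")
  bonds_raw <- c(
    if (!is.null(sec$BONDS_INC_HYDROGEN))
      as.integer(unlist(strsplit(trimws(paste(sec$BONDS_INC_HYDROGEN,
                                              collapse = " ")), "\\s+"))),
    if (!is.null(sec$BONDS_WITHOUT_HYDROGEN))
      as.integer(unlist(strsplit(trimws(paste(sec$BONDS_WITHOUT_HYDROGEN,
                                              collapse = " ")), "\\s+"))))
  bonds <- if (length(bonds_raw)) {
    trip <- matrix(bonds_raw, ncol = 3, byrow = TRUE)
    cbind(trip[, 1] %/% 3L + 1L, trip[, 2] %/% 3L + 1L)  # prmtop stores 3*(i-1)
  } else matrix(integer(0), ncol = 2)
  elements <- .element_from_mass(masses)

  ## molecules = connected components of the bond graph
  adj <- .adjacency(n_atoms, bonds)
  comp <- integer(n_atoms)
  cur <- 0L
  for (a in seq_len(n_atoms)) {
    if (comp[a]) next
    cur <- cur + 1L
    queue <- a
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v]) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  molecules <- split(seq_len(n_atoms), comp)
  names(molecules) <- NULL
  species <- vapply(molecules, function(idx) {
    el <- sort(elements[idx])
    if (identical(el, c("H", "H", "O"))) "water" else "other"
  }, "")
  sigma <- ifelse(species == "water", 2, 1)
  mcc_topology(masses, elements, bonds, molecules, species, sigma)
}

.element_from_mass <- function(masses) {
  ref <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
           P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.9)
  names(ref)[apply(abs(outer(masses, ref, "-")), 1, which.min)]
}
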