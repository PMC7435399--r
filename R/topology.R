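# Topology: molecule membership, site labels, masses, nonbonded parameters.
#
# Site labels follow the usual ionic-liquid / cellulose nomenclature, e.g.
# H(Ring), H(Hyd), H(Cel), O(Car), O(Hyd), O(Cel), H2, H3, H6, O2, O3, O6,
# OA, OB. The vocabulary is open: any label declared in the topology is
# valid, and analyses that receive an undeclared label raise an error.

#' Build a topology from per-species atom definitions
#'
#' @param species named list; each element is a list with `atoms` (a
#'   data.frame with columns `element`, `site_label`, `mass` and optional
#'   `charge`, `sigma`, `epsilon`) and optional `rings` (named list of
#'   within-molecule atom index vectors).
#' @param counts named integer vector: molecules per species, laid out in
#'   the order given. Names may repeat, so interleaved molecule layouts
#'   (e.g. anion, cation, anion, ...) can be declared.
#' @return An object of class `"Topology"` with a flat `atoms` data.frame
#'   (columns `element`, `site_label`, `molecule_id`, `species`, `mass`,
#'   `charge`, `sigma`, `epsilon`), a `molecules` data.frame and the ring
#'   definitions.
#' @export
topology <- function(species, counts) {
  if (is.null(names(species)) || any(!nzchar(names(species))))
    stop("species must be a named list")
  if (!all(names(counts) %in% names(species)))
    stop("counts refer to undeclared species")
  atoms <- list(); mols <- list(); mol_id <- 0L; at0 <- 0L
  for (ci in seq_along(counts)) {
    sp <- names(counts)[ci]
    def <- species[[sp]]$atoms
    req <- c("element", "site_label", "mass")
    if (!all(req %in% names(def)))
      stop(sprintf("species %s: atoms need columns %s", sp,
                   paste(req, collapse = ", ")))
    if (any(def$mass <= 0)) stop(sprintf("species %s: masses must be > 0", sp))
    for (opt in c("charge", "sigma", "epsilon"))
      if (is.null(def[[opt]])) def[[opt]] <- NA_real_
    for (k in seq_len(counts[[ci]])) {
      mol_id <- mol_id + 1L
      a <- def[, c("element", "site_label", "mass", "charge", "sigma", "epsilon")]
      a$molecule_id <- mol_id
      a$species <- sp
      atoms[[mol_id]] <- a
      mols[[mol_id]] <- data.frame(species = sp, molecule_id = mol_id,
                                   first = at0 + 1L, last = at0 + nrow(def))
      at0 <- at0 + nrow(def)
    }
  }
  atoms <- do.call(rbind, atoms)
  rownames(atoms) <- NULL
  rings <- lapply(species, function(s) s$rings)
  structure(list(atoms = atoms, molecules = do.call(rbind, mols),
                 rings = rings), class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms, %d molecules, %d species\n",
              nrow(x$atoms), nrow(x$molecules),
              length(unique(x$atoms$species))))
  invisible(x)
}

#' Atom indices carrying any of the given site labels
#'
#' @param topo a `Topology`.
#' @param labels character vector of site labels.
#' @param species optional species filter.
#' @return integer atom indices.
#' @export
select_sites <- function(topo, labels, species = NULL) {
  known <- unique(topo$atoms$site_label)
  bad <- setdiff(labels, known)
  if (length(bad) > 0)
    stop(sprintf("unknown site label(s): %s", paste(bad, collapse = ", ")))
  sel <- topo$atoms$site_label %in% labels
  if (!is.null(species)) sel <- sel & topo$atoms$species %in% species
  idx <- which(sel)
  if (length(idx) == 0)
    stop(sprintf("empty selection for label(s): %s", paste(labels, collapse = ", ")))
  idx
}

#' Absolute atom indices of a named ring in one molecule
#'
#' @param topo a `Topology`.
#' @param molecule_id molecule.
#' @param ring ring name declared for that molecule's species.
#' @return integer atom indices into the trajectory.
#' @export
ring_indices <- function(topo, molecule_id, ring) {
  m <- topo$molecules[topo$molecules$molecule_id == molecule_id, ]
  if (nrow(m) != 1) stop(sprintf("unknown molecule_id %s", molecule_id))
  r <- topo$rings[[m$species]][[ring]]
  if (is.null(r)) stop(sprintf("species %s has no ring '%s'", m$species, ring))
  m$first - 1L + r
}

#' Read / write a topology as JSON
#'
#' The on-disk format is a structured JSON document declaring species
#' (atom roles, masses, optional charges and Lennard-Jones parameters, ring
#' atom lists) and molecule counts.
#'
#' @param path file path.
#' @return a `Topology`.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(doc$species) || is.null(doc$counts))
    stop(sprintf("topology %s must declare 'species' and 'counts'", path))
  species <- lapply(doc$species, function(s) {
    rings <- if (!is.null(s$rings)) lapply(s$rings, as.integer) else NULL
    list(atoms = as.data.frame(s$atoms), rings = rings)
  })
  cnt <- doc$counts
  if (is.data.frame(cnt)) {            # run-length layout written by write_topology
    counts <- as.integer(cnt$n)
    names(counts) <- cnt$species
  } else {
    counts <- unlist(cnt)
  }
  topology(species, counts)
}

#' @rdname read_topology
#' @param topo a `Topology`.
#' @export
write_topology <- function(topo, path) {
  species <- list()
  for (sp in unique(topo$molecules$species)) {
    m <- topo$molecules[topo$molecules$species == sp, ][1, ]
    at <- topo$atoms[m$first:m$last,
                     c("element", "site_label", "mass", "charge", "sigma", "epsilon")]
    rownames(at) <- NULL
    species[[sp]] <- list(atoms = at)
    if (!is.null(topo$rings[[sp]])) species[[sp]]$rings <- topo$rings[[sp]]
  }
  # run-length layout so interleaved molecule orders survive the round trip
  r <- rle(topo$molecules$species)
  counts <- data.frame(species = r$values, n = r$lengths)
  jsonlite::write_json(list(species = species, counts = counts), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
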