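#' Default neurochemical vocabulary
#'
#' The 25 transmitter/modulator labels that an areal-scale neurochemical
#' connectome typically carries. The first five (GABA, dopamine, serotonin,
#' glutamate, enkephalin) dominate the labelled portion of such networks;
#' the remainder cover the classical amino-acid, monoamine, peptide and
#' lipid systems.
#'
#' @return Character vector of 25 label names.
#' @export
default_chemical_vocabulary <- function() {
  c(
    "GABA", "dopamine", "serotonin", "glutamate", "enkephalin",
    "acetylcholine", "noradrenaline", "histamine", "glycine", "CRF",
    "oxytocin", "vasopressin", "substance-P", "neuropeptide-Y",
    "somatostatin", "cholecystokinin", "dynorphin", "orexin", "galanin",
    "VIP", "endocannabinoid", "ATP", "adenosine", "taurine", "melatonin"
  )
}

#' Construct a connectome object
#'
#' A `connectome` is a directed binary graph over named brain regions.
#' The adjacency matrix `A` has `A[i, j] = 1` iff there is a directed
#' projection from region i to region j; its diagonal is always zero.
#' Intraregional (self) connections are stored apart from `A` in
#' `self_loops`, so that all graph analyses operate on the loop-free
#' interareal network. Edges may carry a set of neurochemical labels drawn
#' from a declared vocabulary; unlabelled edges are plain binary links.
#'
#' @param regions A data frame with at least a column `id` (unique region
#'   keys). Optional columns: `name`, `macro_region`, `x`, `y`, `z`
#'   (stereotaxic coordinates, mm), `bregma` (mm).
#' @param A Square binary adjacency matrix, `nrow(regions)` on a side,
#'   zero diagonal. Row/column order follows `regions`.
#' @param self_loops Character vector of region ids with intraregional
#'   connections.
#' @param chemical Optional tibble with columns `source`, `target`, `label`
#'   (one row per edge-label pair); every (source, target) must be an edge
#'   of `A` and every label must belong to `vocabulary`.
#' @param vocabulary Character vector of allowed chemical labels; defaults
#'   to [default_chemical_vocabulary()].
#'
#' @return An object of class `connectome`.
#' @export
connectome <- function(regions, A = NULL, self_loops = character(),
                       chemical = NULL, vocabulary = default_chemical_vocabulary()) {
  regions <- tibble::as_tibble(regions)
  if (!"id" %in% names(regions)) stop("`regions` must have an `id` column")
  regions$id <- as.character(regions$id)
  if (anyDuplicated(regions$id)) {
    stop("duplicate region ids: ",
         paste(unique(regions$id[duplicated(regions$id)]), collapse = ", "))
  }
  n <- nrow(regions)
  if (is.null(A)) A <- matrix(0L, n, n)
  A <- as.matrix(A)
  if (!all(dim(A) == c(n, n))) stop("`A` must be ", n, "x", n)
  storage.mode(A) <- "integer"
  if (!all(A %in% c(0L, 1L))) stop("`A` must be binary")
  if (any(diag(A) != 0L)) {
    stop("`A` must have a zero diagonal; put intraregional connections in `self_loops`")
  }
  dimnames(A) <- list(regions$id, regions$id)
  self_loops <- as.character(self_loops)
  bad <- setdiff(self_loops, regions$id)
  if (length(bad)) stop("unknown self-loop regions: ", paste(bad, collapse = ", "))
  if (!is.null(chemical)) {
    chemical <- tibble::as_tibble(chemical)
    stopifnot(all(c("source", "target", "label") %in% names(chemical)))
    chemical <- dplyr::distinct(chemical, .data$source, .data$target, .data$label)
    bad_lab <- setdiff(chemical$label, vocabulary)
    if (length(bad_lab)) {
      stop("chemical labels outside the vocabulary: ", paste(bad_lab, collapse = ", "))
    }
    on_edge <- A[cbind(match(chemical$source, regions$id),
                       match(chemical$target, regions$id))]
    if (any(is.na(on_edge)) || any(on_edge == 0L)) {
      off <- chemical[is.na(on_edge) | on_edge == 0L, ]
      stop("chemical labels on non-edges: ",
           paste(paste0(off$source, "->", off$target), collapse = ", "))
    }
  }
  structure(
    list(regions = regions, A = A, self_loops = unique(self_loops),
         chemical = chemical, vocabulary = vocabulary),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", n_regions(x), " regions, ", n_edges(x),
      " directed links, ", length(x$self_loops), " self-loops\n", sep = "")
  if (!is.null(x$chemical)) {
    cov <- length(unique(paste(x$chemical$source, x$chemical$target))) / max(1L, n_edges(x))
    cat("  chemical layer: ", length(unique(x$chemical$label)), " labels, ",
        sprintf("%.1f%%", 100 * cov), " edge coverage\n", sep = "")
  }
  invisible(x)
}

#' Number of regions / directed links
#'
#' @param C A `connectome`.
#' @return Integer count.
#' @export
n_regions <- function(C) nrow(C$regions)

#' @rdname n_regions
#' @export
n_edges <- function(C) sum(C$A)

#' Edge list of a connectome as a tibble
#'
#' @param C A `connectome`.
#' @return Tibble with columns `source`, `target` and, when a chemical layer
#'   is present, a list-column `chemicals`.
#' @export
edge_tibble <- function(C) {
  idx <- which(C$A == 1L, arr.ind = TRUE)
  ids <- C$regions$id
  out <- tibble::tibble(source = ids[idx[, 1]], target = ids[idx[, 2]])
  out <- dplyr::arrange(out, match(.data$source, ids), match(.data$target, ids))
  if (!is.null(C$chemical)) {
    lab <- C$chemical |>
      dplyr::group_by(.data$source, .data$target) |>
      dplyr::summarise(chemicals = list(sort(.data$label)), .groups = "drop")
    out <- dplyr::left_join(out, lab, by = c("source", "target"))
    out$chemicals <- purrr::map(out$chemicals, \(x) if (is.null(x)) character() else x)
  }
  out
}

#' Convert a connectome to an igraph graph
#'
#' @param C A `connectome`.
#' @param mode `"directed"` (the interareal digraph), `"undirected"` (the
#'   simple undirected support, double links collapsed), or `"reciprocal"`
#'   (undirected graph keeping only mutually linked pairs — the graph on
#'   which directed cliques live).
#' @return An `igraph` object with vertex names equal to region ids.
#' @export
as_igraph <- function(C, mode = c("directed", "undirected", "reciprocal")) {
  mode <- match.arg(mode)
  A <- C$A
  if (mode == "undirected") {
    A <- (A | t(A)) * 1L
    return(igraph::graph_from_adjacency_matrix(A, mode = "undirected"))
  }
  if (mode == "reciprocal") {
    A <- (A & t(A)) * 1L
    return(igraph::graph_from_adjacency_matrix(A, mode = "undirected"))
  }
  igraph::graph_from_adjacency_matrix(A, mode = "directed")
}
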