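#' Read a connectome from delimited text tables
#'
#' Reads a region table and an edge table (both TSV) into a [connectome].
#' Edge rows whose source equals their target are recorded as intraregional
#' self-loops and excluded from the adjacency matrix. Region order in all
#' matrices follows the region-table order.
#'
#' @param edge_file TSV with header `source  target` and an optional
#'   `chemicals` column (`;`-separated labels). May have zero rows.
#' @param region_file TSV with header `id  name  macro_region` and optional
#'   `x  y  z  bregma` columns (mm).
#' @param vocabulary Allowed chemical labels; defaults to
#'   [default_chemical_vocabulary()].
#'
#' @return A [connectome].
#' @export
read_connectome <- function(edge_file, region_file,
                            vocabulary = default_chemical_vocabulary()) {
  regions <- readr::read_tsv(region_file, show_col_types = FALSE,
                             col_types = readr::cols(id = "c"))
  edges <- readr::read_tsv(edge_file, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(source = character(), target = character())
  }
  connectome_from_edges(edges, regions, vocabulary = vocabulary)
}

#' Build a connectome from in-memory edge and region tables
#'
#' @inheritParams read_connectome
#' @param edges Data frame with columns `source`, `target` and optionally
#'   `chemicals` (either `;`-separated strings or a list-column).
#' @param regions Data frame as in [read_connectome()].
#' @return A [connectome].
#' @export
connectome_from_edges <- function(edges, regions,
                                  vocabulary = default_chemical_vocabulary()) {
  regions <- tibble::as_tibble(regions)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("source", "target") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)

  dup <- duplicated(edges[c("source", "target")])
  if (any(dup)) {
    off <- unique(paste0(edges$source[dup], "->", edges$target[dup]))
    stop("duplicate edge rows: ", paste(off, collapse = ", "))
  }
  ids <- as.character(regions$id)
  unknown <- setdiff(c(edges$source, edges$target), ids)
  if (length(unknown)) {
    stop("edges reference unknown regions: ", paste(unknown, collapse = ", "))
  }

  is_loop <- edges$source == edges$target
  self_loops <- edges$source[is_loop]
  ee <- edges[!is_loop, , drop = FALSE]
  n <- nrow(regions)
  A <- matrix(0L, n, n)
  A[cbind(match(ee$source, ids), match(ee$target, ids))] <- 1L

  chemical <- NULL
  if ("chemicals" %in% names(edges)) {
    chem_col <- ee$chemicals
    if (!is.list(chem_col)) {
      chem_col <- strsplit(ifelse(is.na(chem_col), "", chem_col), ";", fixed = TRUE)
    }
    chemical <- tibble::tibble(source = ee$source, target = ee$target,
                               label = chem_col) |>
      tidyr::unnest("label") |>
      dplyr::filter(.data$label != "")
    if (nrow(chemical) == 0) chemical <- NULL
  }
  connectome(regions, A, self_loops = self_loops, chemical = chemical,
             vocabulary = vocabulary)
}

#' Write a connectome as a TSV edge-table / region-table pair
#'
#' Lossless counterpart of [read_connectome()]: self-loops appear as rows
#' with `source == target` and chemical label sets as a `;`-joined
#' `chemicals` column.
#'
#' @param C A [connectome].
#' @param edge_file,region_file Output paths.
#' @return Invisibly, `C`.
#' @export
write_connectome <- function(C, edge_file, region_file) {
  readr::write_tsv(C$regions, region_file)
  et <- edge_tibble(C)
  et$chemicals <- if ("chemicals" %in% names(et)) {
    purrr::map_chr(et$chemicals, paste, collapse = ";")
  } else {
    character(nrow(et))
  }
  if (length(C$self_loops)) {
    et <- dplyr::bind_rows(
      et, tibble::tibble(source = C$self_loops, target = C$self_loops,
                         chemicals = ""))
  }
  readr::write_tsv(et, edge_file)
  invisible(C)
}

#' Euclidean inter-centre distance matrix
#'
#' Straight-line distances (mm) between the geometric centres of the brain
#' regions, from their stereotaxic coordinates.
#'
#' @param x A [connectome] or a region data frame with columns `id`, `x`,
#'   `y`, `z`.
#' @return Symmetric N x N matrix (mm) with zero diagonal, dimnames set to
#'   region ids.
#' @export
euclidean_distances <- function(x) {
  regions <- if (inherits(x, "connectome")) x$regions else tibble::as_tibble(x)
  need <- c("x", "y", "z")
  if (!all(need %in% names(regions))) stop("regions lack coordinate columns x, y, z")
  xyz <- as.matrix(regions[, need])
  missing <- !stats::complete.cases(xyz) | !apply(is.finite(xyz), 1, all)
  if (any(missing)) {
    stop("regions lacking finite coordinates: ",
         paste(regions$id[missing], collapse = ", "))
  }
  D <- as.matrix(stats::dist(xyz))
  dimnames(D) <- list(regions$id, regions$id)
  D
}

#' Export a connectome to a standard graph format
#'
#' GraphML keeps regions, coordinates, self-loops and chemical labels
#' (lossless; see [read_graphml()]). The edge-list TSV keeps adjacency,
#' loops and labels but needs the companion region table for a full
#' round-trip. The adjacency CSV (region ids as header row and first
#' column) drops the chemical layer.
#'
#' @param C A [connectome].
#' @param path Output file path.
#' @param format One of `"graphml"`, `"tsv"`, `"adjacency"`.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(C, path, format = c("graphml", "tsv", "adjacency")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- as_igraph(C, "directed")
    r <- C$regions
    for (col in setdiff(names(r), "id")) {
      igraph::vertex_attr(g, col) <- r[[col]]
    }
    igraph::V(g)$self_loop <- as.integer(r$id %in% C$self_loops)
    et <- edge_tibble(C)
    chem <- if ("chemicals" %in% names(et)) {
      purrr::map_chr(et$chemicals, paste, collapse = ";")
    } else rep("", nrow(et))
    # igraph edge order from adjacency matrix is row-major; re-align by key
    el <- igraph::as_edgelist(g)
    key_g <- paste(el[, 1], el[, 2])
    key_t <- paste(et$source, et$target)
    igraph::E(g)$chemicals <- chem[match(key_g, key_t)]
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "tsv") {
    et <- edge_tibble(C)
    et$chemicals <- if ("chemicals" %in% names(et)) {
      purrr::map_chr(et$chemicals, paste, collapse = ";")
    } else ""
    if (length(C$self_loops)) {
      et <- dplyr::bind_rows(
        et, tibble::tibble(source = C$self_loops, target = C$self_loops,
                           chemicals = ""))
    }
    readr::write_tsv(et, path)
  } else {
    df <- as.data.frame(C$A)
    df <- cbind(id = C$regions$id, df)
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' Read a connectome back from GraphML
#'
#' Inverse of `export_graph(..., format = "graphml")`.
#'
#' @param path GraphML file written by [export_graph()].
#' @param vocabulary Allowed chemical labels.
#' @return A [connectome].
#' @export
read_graphml <- function(path, vocabulary = default_chemical_vocabulary()) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  ids <- va$name
  keep <- setdiff(names(va), c("name", "self_loop", "id"))
  regions <- tibble::as_tibble(c(list(id = ids), va[keep]))
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  self_loops <- if (!is.null(va$self_loop)) ids[va$self_loop == 1] else character()
  chemical <- NULL
  ea <- igraph::edge_attr(g, "chemicals")
  if (!is.null(ea)) {
    el <- igraph::as_edgelist(g)
    chemical <- tibble::tibble(source = el[, 1], target = el[, 2],
                               label = strsplit(ifelse(is.na(ea), "", ea), ";")) |>
      tidyr::unnest("label") |>
      dplyr::filter(.data$label != "")
    if (nrow(chemical) == 0) chemical <- NULL
  }
  connectome(regions, A, self_loops = self_loops, chemical = chemical,
             vocabulary = vocabulary)
}
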