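#' ROI sets for seed-based connectivity
#'
#' An ROI set is an ordered table of network nodes (name, resting-state
#' network, MNI coordinate in mm, sphere radius, seed flag) together with the
#' derived seed-edge list.  The default set holds the 17 nodes of the four
#' canonical networks (SMN, DMN, FPN, SN) with the MPFC and PCC as seeds; the
#' extended set adds two visual and two auditory nodes used for the
#' network-specificity analysis.
#'
#' The edge rule is: every seed paired with every other node, and the
#' seed-seed pair (MPFC-PCC, the DMN core) emitted once.  That yields 31
#' edges for the default set and 39 for the extended set; both counts are
#' asserted at construction.
#'
#' @param df data frame with columns `name`, `network`, `x`, `y`, `z`,
#'   `radius`, `is_seed`.
#' @param seed_seed_edge include the seed-seed (MPFC-PCC) edge? Default TRUE.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(df, seed_seed_edge = TRUE) {
  req <- c("name", "network", "x", "y", "z", "radius", "is_seed")
  if (!all(req %in% names(df))) {
    stop("ROI table must have columns: ", paste(req, collapse = " "))
  }
  networks <- c("SMN", "DMN", "FPN", "SN", "VIS", "AUD")
  if (!all(df$network %in% networks)) {
    stop("unknown network label(s): ",
         paste(setdiff(unique(df$network), networks), collapse = ", "))
  }
  if (anyDuplicated(df$name)) stop("ROI names must be unique within a set")
  if (any(df$radius <= 0)) stop("ROI radius must be positive")
  stopifnot_finite(as.matrix(df[, c("x", "y", "z")]), "ROI coordinates")
  df$is_seed <- as.logical(df$is_seed)
  if (sum(df$is_seed) < 1) stop("ROI set needs at least one seed region")

  seeds <- df$name[df$is_seed]
  others <- df$name[!df$is_seed]
  net <- setNames(df$network, df$name)

  edge <- list()
  for (s in seeds) {
    for (t in others) {
      edge[[length(edge) + 1L]] <- data.frame(
        seed = s, target = t, label = paste0(s, "->", t),
        group = net[[t]], stringsAsFactors = FALSE)
    }
  }
  if (seed_seed_edge && length(seeds) >= 2) {
    pairs <- utils::combn(seeds, 2)
    for (j in seq_len(ncol(pairs))) {
      s <- pairs[1, j]; t <- pairs[2, j]
      grp <- if (net[[s]] == "DMN" && net[[t]] == "DMN") "DMN-core" else net[[t]]
      edge[[length(edge) + 1L]] <- data.frame(
        seed = s, target = t, label = paste0(s, "->", t),
        group = grp, stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, edge)
  rownames(edges) <- NULL

  ns <- length(seeds); nr <- nrow(df)
  expected <- ns * (nr - ns) + if (seed_seed_edge) choose(ns, 2) else 0
  stopifnot(nrow(edges) == expected)
  # the two packaged fixtures must give the canonical 31/39 edge counts
  if (seed_seed_edge && ns == 2 && nr == 17) stopifnot(nrow(edges) == 31L)
  if (seed_seed_edge && ns == 2 && nr == 21) stopifnot(nrow(edges) == 39L)

  structure(list(roi = df, edges = edges, seeds = seeds),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("ROI set:", nrow(x$roi), "nodes,", nrow(x$edges), "seed edges\n")
  cat("seeds:", paste(x$seeds, collapse = ", "), "\n")
  cat("networks:", paste(sort(unique(x$roi$network)), collapse = ", "), "\n")
  invisible(x)
}

#' Read an ROI table from TSV
#'
#' Expected header: `name network x y z radius is_seed`.
#' @param path TSV file path.
#' @param ... passed to [roi_set()].
#' @export
read_roi_table <- function(path, ...) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  roi_set(df, ...)
}

#' The packaged ROI sets
#'
#' `default_roi_set()` returns the 17-node SMN/DMN/FPN/SN set with MPFC and
#' PCC seeds (31 edges); with `extended = TRUE` the 21-node set that adds the
#' bilateral visual and auditory nodes (39 edges).  Coordinates are shipped
#' verbatim from the source coordinate table (including the anterior-y visual
#' coordinates, which are not sign-corrected).
#'
#' @param extended include the visual/auditory nodes?
#' @export
default_roi_set <- function(extended = FALSE) {
  f <- if (extended) "roi_extended.tsv" else "roi_default.tsv"
  read_roi_table(system.file("extdata", f, package = "fcmkl", mustWork = TRUE))
}

# lesion-group of each edge: DMN-core edges belong to the DMN group
edge_lesion_group <- function(group) ifelse(group == "DMN-core", "DMN", group)
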