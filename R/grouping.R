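# Collapse redundant secondary motifs into clusters (e.g. ETS1 and ELF1
# into one ETS cluster) and re-rank by the representative's p-value.

#' Cluster redundant secondary motifs of a screen
#'
#' Single-linkage clustering: two secondary motifs are joined whenever their
#' [motif_similarity()] reaches `sim_threshold`; clusters are the connected
#' components of that graph. Each cluster is represented by its member with
#' the smallest adjusted p-value and clusters are ranked by that value.
#'
#' @param results A `spice_screen` from [analyze_library()], or a
#'   `data.frame` of pair results with columns `secondary`, `gap`,
#'   `quadrant`, `p_adj`, `evalue`.
#' @param db The [motif_db()] the secondaries came from.
#' @param sim_threshold Pearson similarity threshold (default 0.8).
#' @param min_overlap Minimum aligned columns for the similarity.
#' @return An object of class `motif_clusters`: a `data.frame` with one row
#'   per cluster (`cluster_id`, `label`, `n_members`, `members`, plus the
#'   representative's `gap`, `quadrant`, `p_adj`, `evalue`), ranked by
#'   `p_adj`; attribute `membership` maps each secondary to its cluster.
#' @export
cluster_results <- function(results, db, sim_threshold = 0.8,
                            min_overlap = 5L) {
  if (inherits(results, "spice_screen")) results <- results$significant
  if (!nrow(results)) {
    out <- data.frame(cluster_id = integer(), label = character(),
                      n_members = integer(), members = character(),
                      gap = integer(), quadrant = character(),
                      p_adj = numeric(), evalue = numeric())
    class(out) <- c("motif_clusters", "data.frame")
    return(out)
  }
  missing <- setdiff(results$secondary, names(db))
  if (length(missing))
    stop("secondary motif(s) absent from database: ",
         paste(missing, collapse = ", "))
  nms <- results$secondary
  p <- length(nms)
  adj <- matrix(FALSE, p, p)
  if (p > 1L) {
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
      mo <- min(min_overlap, db[[nms[i]]]$width, db[[nms[j]]]$width)
      adj[i, j] <- adj[j, i] <-
        motif_similarity(db[[nms[i]]], db[[nms[j]]], mo) >= sim_threshold
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  reps <- vapply(seq_len(max(comp)), function(cl) {
    members <- which(comp == cl)
    members[which.min(results$p_adj[members])]
  }, integer(1))
  out <- data.frame(
    cluster_id = seq_along(reps),
    label = nms[reps],
    n_members = as.integer(table(comp)[as.character(seq_along(reps))]),
    members = vapply(seq_along(reps), function(cl)
      paste(nms[comp == cl], collapse = ","), character(1)),
    gap = results$gap[reps], quadrant = results$quadrant[reps],
    p_adj = results$p_adj[reps], evalue = results$evalue[reps],
    stringsAsFactors = FALSE)
  ord <- order(out$p_adj, out$gap, out$label)
  out <- out[ord, , drop = FALSE]
  out$cluster_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  member_lists <- strsplit(out$members, ",", fixed = TRUE)
  membership <- stats::setNames(vapply(nms, function(nm)
    which(vapply(member_lists, function(ml) nm %in% ml, logical(1)))[1],
    integer(1)), nms)
  attr(out, "membership") <- membership
  class(out) <- c("motif_clusters", "data.frame")
  out
}

#' @export
print.motif_clusters <- function(x, ...) {
  cat("<motif_clusters> ", nrow(x), " cluster(s)\n", sep = "")
  print.data.frame(utils::head(x, 10L))
  invisible(x)
}

#' Write clusters as TSV
#'
#' @param clusters A `motif_clusters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(clusters, path) {
  utils::write.table(as.data.frame(clusters), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
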