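#' Correlation distance between cross-tissue concentration profiles
#'
#' Each peak is summarized by its mean normalized concentration in every
#' (species, tissue) cell (up to 20 values with four species and five
#' tissues); the distance between two peaks is 1 minus the Pearson
#' correlation of their profiles. Peaks with zero-variance profiles get the
#' maximal distance (2) to every other peak and are flagged in the
#' `"degenerate"` attribute.
#'
#' @param mset a normalized [metabolome_set()].
#' @return A symmetric peak x peak distance matrix (base R matrix) with
#'   attribute `"profiles"` (the peak x cell profile matrix).
#' @export
profile_distance <- function(mset) {
  if (nrow(mset$intensities) < 2) abort("need at least 2 peaks")
  smp <- mset$samples
  keep <- smp$sample_id %in% analysis_samples(smp)
  X <- mset$intensities[, keep, drop = FALSE]
  cell <- paste(smp$species[keep], smp$tissue[keep], sep = ".")
  cells <- unique(cell)
  prof <- matrix(NA_real_, nrow(X), length(cells),
                 dimnames = list(rownames(X), cells))
  for (k in seq_along(cells)) {
    j <- which(cell == cells[k])
    prof[, k] <- rowMeans(X[, j, drop = FALSE], na.rm = TRUE)
  }
  sds <- apply(prof, 1, sd, na.rm = TRUE)
  degenerate <- which(!is.finite(sds) | sds == 0)
  cors <- suppressWarnings(stats::cor(t(prof), use = "pairwise.complete.obs"))
  D <- 1 - cors
  if (length(degenerate) > 0) {
    D[degenerate, ] <- 2
    D[, degenerate] <- 2
  }
  diag(D) <- 0
  structure(D, profiles = prof,
            degenerate = rownames(prof)[degenerate])
}

#' Complete-linkage clustering with silhouette-chosen cluster count
#'
#' Builds a complete-linkage dendrogram from the profile distance matrix,
#' cuts it at every k in `k_range`, computes the mean silhouette width at
#' each k, and keeps the k with the maximal mean silhouette (the smallest
#' k on ties).
#'
#' @param dist_mat symmetric distance matrix (e.g. [profile_distance()]).
#' @param k_range integer candidate cluster counts, within
#'   `[2, n_peaks - 1]` (default `2:30`).
#' @return A `peak_clustering`: list with `membership` (tibble `peak_id`,
#'   `cluster`), `silhouette` (tibble `k`, `mean_silhouette`), `k`,
#'   `hclust`.
#' @export
cluster_peaks <- function(dist_mat, k_range = 2:30) {
  n <- nrow(dist_mat)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) abort("`k_range` empty after bounding")
  off <- dist_mat[upper.tri(dist_mat)]
  if (max(off) - min(off) < 1e-12) {
    abort("all pairwise distances equal; clustering is degenerate")
  }
  d <- as.dist(dist_mat)
  hc <- hclust(d, method = "complete")
  sil <- purrr::map_dbl(k_range, function(k) {
    cl <- cutree(hc, k = k)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  })
  best <- k_range[which.max(sil)] # which.max takes the first (smallest k)
  cl <- cutree(hc, k = best)
  structure(
    list(
      membership = tibble(peak_id = rownames(dist_mat) %||%
                            as.character(seq_len(n)),
                          cluster = unname(cl)),
      silhouette = tibble(k = k_range, mean_silhouette = sil),
      k = best, hclust = hc
    ),
    class = "peak_clustering"
  )
}

#' @export
print.peak_clustering <- function(x, ...) {
  cat("<peak_clustering> k = ", x$k, " clusters over ",
      nrow(x$membership), " peaks (mean silhouette ",
      signif(max(x$silhouette$mean_silhouette), 3), ")\n", sep = "")
  invisible(x)
}

#' @describeIn cluster_peaks peak-to-cluster membership tibble (dropped
#'   peaks labelled `"dropped"`).
#' @param x a `peak_clustering`.
#' @param ... unused.
#' @method tidy peak_clustering
#' @export
tidy.peak_clustering <- function(x, ...) x$membership

#' @describeIn cluster_peaks silhouette-vs-k curve with the chosen k marked.
#' @param object a `peak_clustering`.
#' @method autoplot peak_clustering
#' @export
autoplot.peak_clustering <- function(object, ...) {
  ggplot2::ggplot(object$silhouette,
                  ggplot2::aes(x = .data$k, y = .data$mean_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters", y = "mean silhouette width") +
    ggplot2::theme_minimal()
}

#' Drop the smallest clusters up to a cumulative mass bound
#'
#' Iteratively marks the smallest clusters as `"dropped"` while the
#' cumulative dropped fraction of peaks stays strictly below `threshold`.
#'
#' @param result a `peak_clustering`.
#' @param threshold maximal cumulative dropped fraction (default 0.10).
#' @return The `peak_clustering` with dropped peaks relabelled
#'   `"dropped"` in `membership$cluster` (stored as character).
#' @export
drop_small_clusters <- function(result, threshold = 0.10) {
  memb <- result$membership
  sizes <- memb |>
    count(.data$cluster, name = "size") |>
    arrange(.data$size, .data$cluster)
  total <- nrow(memb)
  dropped <- character(0)
  cum <- 0L
  for (i in seq_len(nrow(sizes))) {
    if ((cum + sizes$size[i]) / total < threshold) {
      dropped <- c(dropped, as.character(sizes$cluster[i]))
      cum <- cum + sizes$size[i]
    } else {
      break
    }
  }
  memb$cluster <- as.character(memb$cluster)
  memb$cluster[memb$cluster %in% dropped] <- "dropped"
  result$membership <- memb
  result$dropped_clusters <- dropped
  result
}

#' Assign a tissue specificity label to each cluster
#'
#' A cluster is labelled with the tissue whose cluster-mean profile value
#' (averaged over species) deviates most, in absolute value, from the
#' cluster's cross-tissue mean; the direction is the sign of that
#' deviation. Exact ties across tissues are labelled `"ambiguous"`.
#'
#' @param result a `peak_clustering` (possibly after
#'   [drop_small_clusters()]).
#' @param mset the normalized [metabolome_set()] the clustering came from.
#' @return Tibble `cluster`, `tissue`, `direction`, `deviation`.
#' @export
assign_tissue_specificity <- function(result, mset) {
  D <- profile_distance(mset) # reuse the (species, tissue) cell profiles
  prof <- attr(D, "profiles")
  cells <- strsplit(colnames(prof), ".", fixed = TRUE)
  cell_tissue <- purrr::map_chr(cells, 2)
  memb <- result$membership |> filter(.data$cluster != "dropped")
  out <- list()
  for (cl in unique(memb$cluster)) {
    ids <- memb$peak_id[memb$cluster == cl]
    m <- colMeans(prof[ids, , drop = FALSE], na.rm = TRUE)
    by_tissue <- tapply(m, cell_tissue, mean, na.rm = TRUE)
    dev <- by_tissue - mean(by_tissue)
    top <- which(abs(dev) == max(abs(dev)))
    if (length(top) > 1) {
      out[[cl]] <- tibble(cluster = cl, tissue = "ambiguous",
                          direction = NA_character_, deviation = NA_real_)
    } else {
      out[[cl]] <- tibble(
        cluster = cl, tissue = names(by_tissue)[top],
        direction = unname(ifelse(dev[top] > 0, "up", "down")),
        deviation = unname(dev[top])
      )
    }
  }
  bind_rows(out) |> arrange(.data$cluster)
}
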