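#' Regress per-lineage divergence proportions on branch lengths
#'
#' The proportion of tested peaks assigned to each lineage in each tissue
#' category measures metabolome divergence on that lineage. An ordinary
#' least-squares line is fitted through the nonhuman points (three nonhuman
#' lineages x seven tissue categories = 21 points) as a function of branch
#' length in million years; the human points are then compared with the
#' fit: per tissue, the predicted human proportion at the human branch
#' length, the observed/predicted excess, the human/chimpanzee fold excess,
#' and a one-sided p value for the human point exceeding the regression
#' prediction (studentized prediction residual against the nonhuman fit).
#'
#' @param assign a `lineage_assignment` from [classify_species_specific()]
#'   (or its assignments tibble).
#' @param tested tibble `tissue`, `lineage`, `n_tested` giving the number
#'   of peaks tested per point; taken from `assign$families` when omitted.
#' @param phylo a [make_phylogeny()].
#' @return A `divergence_fit` with `points`, `human` and `fit` components;
#'   see [tidy.divergence_fit()] and [glance.divergence_fit()].
#' @export
divergence_regression <- function(assign, tested = NULL,
                                  phylo = make_phylogeny()) {
  tbl <- if (inherits(assign, "lineage_assignment")) assign$assignments else
    as_tibble(assign)
  if (is.null(tested)) {
    if (!inherits(assign, "lineage_assignment")) {
      abort("supply `tested` counts when `assign` is a plain tibble")
    }
    tested <- assign$families |>
      select("tissue", "lineage", "n_tested")
  }
  counts <- tbl |>
    distinct(.data$peak_id, .data$tissue, .data$lineage) |>
    count(.data$tissue, .data$lineage, name = "n_assigned")
  points <- tested |>
    left_join(counts, by = c("tissue", "lineage")) |>
    mutate(
      n_assigned = tidyr::replace_na(.data$n_assigned, 0L),
      branch_my = unname(phylo$lineage_lengths[.data$lineage]),
      proportion = ifelse(.data$n_tested > 0,
                          .data$n_assigned / .data$n_tested, NA_real_)
    )
  nh <- points |> filter(.data$lineage != "human", !is.na(.data$proportion))
  if (nrow(nh) < 3) abort("need at least 3 nonhuman points to fit")
  x <- nh$branch_my
  y <- nh$proportion
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  if (sxx > 0) {
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    intercept <- mean(y) - slope * mean(x)
    fitted_nh <- intercept + slope * x
    rss <- sum((y - fitted_nh)^2)
    s2 <- rss / (n - 2)
    r2 <- if (stats::sd(y) > 0) stats::cor(x, y)^2 else NA_real_
  } else {
    # a single distinct branch length: no regression, ratios only
    slope <- intercept <- r2 <- s2 <- NA_real_
  }

  hm <- points |> filter(.data$lineage == "human")
  x0 <- hm$branch_my
  if (is.na(slope)) {
    pred <- t_excess <- p_excess <- rep(NA_real_, nrow(hm))
  } else {
    pred <- intercept + slope * x0
    se_pred <- sqrt(s2 * (1 + 1 / n + (x0 - mean(x))^2 / sxx))
    t_excess <- (hm$proportion - pred) / se_pred
    p_excess <- pt(t_excess, df = n - 2, lower.tail = FALSE)
  }
  chimp <- points |>
    filter(.data$lineage == "chimp") |>
    select("tissue", chimp_proportion = "proportion")
  human <- hm |>
    select("tissue", human_proportion = "proportion",
           n_assigned_human = "n_assigned") |>
    mutate(predicted = pred, excess = .data$human_proportion / pred,
           statistic = t_excess, p_excess = p_excess) |>
    left_join(chimp, by = "tissue") |>
    mutate(
      fold_vs_chimp = .data$human_proportion / .data$chimp_proportion,
      fold_flag = ifelse(.data$chimp_proportion == 0, "infinite", "ok")
    )
  structure(
    list(points = points, human = human,
         fit = list(slope = slope, intercept = intercept, r_squared = r2,
                    n = n, sigma = sqrt(s2), df = n - 2)),
    class = "divergence_fit"
  )
}

#' @export
print.divergence_fit <- function(x, ...) {
  cat("<divergence_fit> slope ", signif(x$fit$slope, 4), "/MY, r^2 ",
      signif(x$fit$r_squared, 3), " (n = ", x$fit$n, " nonhuman points)\n",
      sep = "")
  invisible(x)
}

#' @describeIn divergence_regression one row per (tissue, lineage) point
#'   with the fitted value and residual under the nonhuman regression.
#' @param x a `divergence_fit`.
#' @param ... unused.
#' @method tidy divergence_fit
#' @export
tidy.divergence_fit <- function(x, ...) {
  x$points |>
    mutate(.fitted = x$fit$intercept + x$fit$slope * .data$branch_my,
           .resid = .data$proportion - .data$.fitted)
}

#' @describeIn divergence_regression one-row model summary.
#' @method glance divergence_fit
#' @export
glance.divergence_fit <- function(x, ...) {
  tibble(slope = x$fit$slope, intercept = x$fit$intercept,
         r_squared = x$fit$r_squared, sigma = x$fit$sigma, n = x$fit$n)
}

#' @describeIn divergence_regression divergence vs branch length, nonhuman
#'   points with the fitted line and human points as asterisks.
#' @param object a `divergence_fit`.
#' @method autoplot divergence_fit
#' @export
autoplot.divergence_fit <- function(object, ...) {
  pts <- tidy(object)
  nh <- pts |> filter(.data$lineage != "human")
  hm <- pts |> filter(.data$lineage == "human")
  ggplot2::ggplot(nh, ggplot2::aes(x = .data$branch_my,
                                   y = .data$proportion)) +
    ggplot2::geom_abline(intercept = object$fit$intercept,
                         slope = object$fit$slope, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$tissue), size = 2) +
    ggplot2::geom_point(data = hm,
                        ggplot2::aes(colour = .data$tissue),
                        shape = 8, size = 3, stroke = 1.2) +
    ggplot2::labs(x = "branch length (MY)",
                  y = "proportion of peaks with significant divergence",
                  colour = "tissue") +
    ggplot2::theme_minimal()
}

#' Relative concentration matrix across primates
#'
#' For each primate sample, each peak's concentration is expressed as the
#' base-2 log ratio to the mean concentration across all samples of the
#' other primate species within the same tissue.
#'
#' @param mset a [metabolome_set()] of primate samples; with
#'   `input = "log2"` (default, i.e. a normalized set) values are converted
#'   back to the linear scale for the comparison mean.
#' @param input `"log2"` or `"linear"` scale of the stored values.
#' @return A peaks x samples matrix of log2 ratios (primate individual
#'   samples only).
#' @export
relative_concentration_matrix <- function(mset, input = c("log2", "linear")) {
  input <- match.arg(input)
  smp <- mset$samples
  keep <- smp$sample_id %in% analysis_samples(smp) &
    smp$species %in% c("human", "chimpanzee", "macaque")
  if (!any(keep)) abort("no primate individual samples present")
  sub <- subset_mset(mset, samples = which(keep))
  X <- sub$intensities
  lin <- if (input == "log2") 2^X else X
  logx <- if (input == "log2") X else log2(X)
  out <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  for (t in unique(sub$samples$tissue)) {
    jt <- which(sub$samples$tissue == t)
    for (sp in unique(sub$samples$species[jt])) {
      j_sp <- jt[sub$samples$species[jt] == sp]
      j_other <- jt[sub$samples$species[jt] != sp]
      if (length(j_other) == 0) {
        abort(sprintf("no other-primate samples for %s in tissue %s", sp, t))
      }
      ref <- log2(rowMeans(lin[, j_other, drop = FALSE], na.rm = TRUE))
      out[, j_sp] <- logx[, j_sp, drop = FALSE] - ref
    }
  }
  out
}
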