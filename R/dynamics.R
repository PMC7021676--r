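#' Per-frame inter-mouse distance
#'
#' Euclidean distance between the two mice on the video clock. Centroids
#' are the default body point (the most stable tracked point);
#' nose-to-nose is available via `point = "nose"`. Frames missing from
#' either track give `NA`.
#'
#' @param tracks tracks data.frame (see [simulate_dyad()]).
#' @param point `"centroid"` or `"nose"`.
#' @return numeric vector indexed by frame, cm.
#' @export
interanimal_distance <- function(tracks, point = c("centroid", "nose")) {
  point <- match.arg(point)
  cols <- if (point == "centroid") c("centroid_x_cm", "centroid_y_cm")
          else c("nose_x_cm", "nose_y_cm")
  n <- max(tracks$frame)
  out <- rep(NA_real_, n)
  t1 <- tracks[tracks$mouse_id == 1, ]
  t2 <- tracks[tracks$mouse_id == 2, ]
  common <- intersect(t1$frame, t2$frame)
  p1 <- as.matrix(t1[match(common, t1$frame), cols])
  p2 <- as.matrix(t2[match(common, t2$frame), cols])
  out[common] <- sqrt(rowSums((p1 - p2)^2))
  miss <- setdiff(seq_len(n), common)
  if (length(miss)) message(length(miss), " frames lack both tracks; masked")
  out
}

#' Fraction of time spent in close proximity
#'
#' Fraction of defined frames with inter-mouse distance strictly below
#' `threshold`, overall and within consecutive time bins. Masked frames are
#' excluded from both numerator and denominator.
#'
#' @param dist per-frame distance vector, cm.
#' @param threshold proximity threshold, cm (20 cm standard).
#' @param bin_s bin width, s.
#' @param frame_rate frames per second.
#' @return list: `overall` fraction, `per_bin` data.frame (`bin`,
#'   `start_s`, `fraction`).
#' @export
proximity_profile <- function(dist, threshold = 20, bin_s = 60,
                              frame_rate = 30) {
  stopifnot(threshold > 0)
  close <- dist < threshold
  bins <- (seq_along(dist) - 1) %/% (bin_s * frame_rate)
  per <- tapply(close, bins, function(z) mean(z, na.rm = TRUE))
  list(overall = mean(close, na.rm = TRUE),
       per_bin = data.frame(bin = as.integer(names(per)) + 1L,
                            start_s = as.integer(names(per)) * bin_s,
                            fraction = as.numeric(per)))
}

#' Time by which a mouse has emitted a given fraction of its signals
#'
#' The time of the `ceiling(q * N)`-th emission — the point where the
#' cumulative emission count (a step function) first reaches fraction `q`.
#'
#' @param times sorted or unsorted emission times of one mouse, s.
#' @param q fraction in (0, 1].
#' @return time in s, or `NA` when the mouse emitted no signals.
#' @export
time_to_fraction_emitted <- function(times, q = 0.5) {
  stopifnot(q > 0, q <= 1)
  if (!length(times)) return(NA_real_)
  sort(times)[ceiling(q * length(times))]
}

#' Median and IQR of inter-mouse distance at emission
#'
#' @param events attributed events data.frame with `frame` and a vocalizer
#'   column (`vocalizer_id` or `assigned_to`).
#' @param dist per-frame distance vector, cm.
#' @return data.frame per mouse: `mouse_id`, `n`, `median_cm`, `iqr_lo_cm`,
#'   `iqr_hi_cm`.
#' @export
emission_distance_stats <- function(events, dist) {
  voc <- events$vocalizer_id %||% events$assigned_to
  d <- dist[events$frame]
  out <- lapply(sort(unique(voc[!is.na(voc)])), function(m) {
    dm <- d[!is.na(voc) & voc == m]
    qs <- stats::quantile(dm, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    data.frame(mouse_id = m, n = length(dm),
               median_cm = stats::median(dm, na.rm = TRUE),
               iqr_lo_cm = qs[1], iqr_hi_cm = qs[2])
  })
  do.call(rbind, out)
}

#' Group comparison with small-sample nonparametric policy
#'
#' Two groups with any n < 15: Mann-Whitney (the reported statistic is the
#' smaller of the two rank sums). Three or more groups with any n < 15:
#' Kruskal-Wallis (df = k - 1) with Dunn's post-hoc (Bonferroni-adjusted).
#' All n >= 15: Welch t-test (2 groups) or one-way ANOVA with Tukey HSD.
#'
#' @param groups named or unnamed list of numeric vectors (>= 2 groups,
#'   each non-empty).
#' @return list: `test`, `statistic`, `df` (when defined), `p.value`,
#'   `posthoc` (data.frame or NULL).
#' @export
group_compare <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0))
    stop("need >= 2 non-empty groups", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  small <- any(lengths(groups) < 15)
  vals <- unlist(groups, use.names = FALSE)
  gl <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(groups) == 2) {
    if (small) {
      wt <- stats::wilcox.test(groups[[1]], groups[[2]], exact = FALSE,
                               correct = FALSE)
      rk <- rank(vals)
      rs <- tapply(rk, gl, sum)
      list(test = "mann_whitney", statistic = unname(min(rs)), df = NA,
           p.value = wt$p.value, posthoc = NULL)
    } else {
      tt <- stats::t.test(groups[[1]], groups[[2]])
      list(test = "t_test", statistic = unname(tt$statistic),
           df = unname(tt$parameter), p.value = tt$p.value, posthoc = NULL)
    }
  } else {
    if (small) {
      kw <- stats::kruskal.test(vals, gl)
      list(test = "kruskal_wallis", statistic = unname(kw$statistic),
           df = unname(kw$parameter), p.value = kw$p.value,
           posthoc = dunn_posthoc(vals, gl))
    } else {
      fit <- stats::aov(vals ~ gl)
      an <- summary(fit)[[1]]
      tk <- stats::TukeyHSD(fit)$gl
      list(test = "anova", statistic = an$`F value`[1],
           df = an$Df[1], p.value = an$`Pr(>F)`[1],
           posthoc = data.frame(comparison = rownames(tk),
                                diff = tk[, "diff"], p.adj = tk[, "p adj"],
                                row.names = NULL))
    }
  }
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the standard tie correction,
#' Bonferroni-adjusted p values.
#'
#' @param values numeric vector of all observations.
#' @param groups factor of group labels.
#' @return data.frame: `comparison`, `z`, `p.unadj`, `p.adj`.
#' @export
dunn_posthoc <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(rk, groups, mean)
  n <- table(groups)
  lv <- levels(groups)
  out <- list()
  for (i in seq_len(length(lv) - 1)) for (j in seq(i + 1, length(lv))) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
    z <- (mean_rank[i] - mean_rank[j]) / se
    out[[length(out) + 1]] <- data.frame(
      comparison = paste(lv[i], "-", lv[j]), z = unname(z),
      p.unadj = unname(2 * stats::pnorm(-abs(z))))
  }
  res <- do.call(rbind, out)
  res$p.adj <- pmin(res$p.unadj * nrow(res), 1)
  res
}
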