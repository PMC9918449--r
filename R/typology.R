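#' Six growth-phase bins for stress trajectories
#'
#' Half-open growth-stage intervals (on the 0-100 scale, see
#' [stage_to_zadoks()]) over which daily photosynthetic stress is averaged:
#' early juvenile JV1 \[10,21), late juvenile JV2 \[21,32), floral initiation
#' to heading FIN \[32,65), flowering to grain filling FL \[65,71), early
#' grain filling GF1 \[71,80), late grain filling GF2 \[80,87). (Published
#' figure captions label both \[32,65) and \[65,71) "FIN"; the second is
#' renamed FL here.)
#'
#' @return A data.frame with columns `bin`, `from`, `to`.
#' @export
phase_bins <- function() {
  data.frame(
    bin = c("JV1", "JV2", "FIN", "FL", "GF1", "GF2"),
    from = c(10, 21, 32, 65, 71, 80),
    to = c(21, 32, 65, 71, 80, 87)
  )
}

#' Phase-mean stress vector of a season
#'
#' Collapses the daily `oxdef_photo` trajectory of one season into a
#' six-element vector of phase means (1 = no stress in the phase), plus
#' companion counts of waterlogged days (days with `oxdef_photo < 1`) per
#' phase. A phase the crop never entered is `NA` (the season is incomplete
#' for clustering purposes).
#'
#' @param season A `season_result` from [simulate_season()], or its `daily`
#'   data.frame (columns `zadoks`, `oxdef_photo`).
#' @param bins Phase bins, see [phase_bins()].
#' @return A list with `stress` (named numeric, 6 phase means),
#'   `waterlogged_days` (named integer, 6 counts), `complete` (no `NA`
#'   phase).
#' @examples
#' w <- generate_weather(weather_gen_params(seed = 3), 2, 2000)
#' s <- generate_soil("freely_drained", seed = 1)
#' res <- simulate_season(w, s, genotype_preset("spring_susceptible"),
#'                        management(90))
#' phase_stress_vector(res)
#' @export
phase_stress_vector <- function(season, bins = phase_bins()) {
  daily <- if (inherits(season, "season_result")) season$daily else season
  if (!is.data.frame(daily) || nrow(daily) == 0) {
    stop("empty trajectory")
  }
  stopifnot(all(c("zadoks", "oxdef_photo") %in% names(daily)))
  stress <- numeric(nrow(bins))
  wl_days <- integer(nrow(bins))
  for (b in seq_len(nrow(bins))) {
    in_bin <- daily$zadoks >= bins$from[b] & daily$zadoks < bins$to[b]
    if (!any(in_bin)) {
      stress[b] <- NA_real_
      wl_days[b] <- NA_integer_
    } else {
      stress[b] <- mean(daily$oxdef_photo[in_bin])
      wl_days[b] <- sum(daily$oxdef_photo[in_bin] < 1)
    }
  }
  names(stress) <- names(wl_days) <- bins$bin
  list(stress = stress, waterlogged_days = wl_days,
       complete = !anyNA(stress))
}

#' Fit a seasonal waterlogging-stress typology by k-means
#'
#' Partitions seasonal stress vectors into `k` clusters (default 4) by
#' Lloyd's algorithm with k-means++ seeding, minimising total within-cluster
#' sums of squares over `n_restarts` seeded restarts. Empty clusters are
#' re-seeded from the point farthest from its centroid. Deterministic under a
#' fixed seed.
#'
#' @param vectors A numeric matrix (rows = seasons, 6 phase columns) or a
#'   list of stress vectors from [phase_stress_vector()]. Rows with `NA`
#'   (incomplete seasons) are dropped with a message.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param n_restarts Number of k-means++ restarts.
#' @param max_iter Lloyd iteration cap per restart.
#' @return A `stress_typology` list: `k`, `centroids` (k x 6 matrix),
#'   `assignments` (cluster index per season), `within_ss`, `total_ss`,
#'   `variance_explained`, `labels` (filled by [label_clusters()]).
#' @export
fit_typology <- function(vectors, k = 4, seed = 1L, n_restarts = 10,
                         max_iter = 100) {
  x <- as_stress_matrix(vectors)
  keep <- stats::complete.cases(x)
  if (!all(keep)) {
    message("dropping ", sum(!keep), " incomplete season(s) from clustering")
  }
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < k) stop("need at least k = ", k, " complete stress vectors")

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centres <- kmeanspp_init(x, k)
      fit <- lloyd_kmeans(x, centres, max_iter)
      if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
    }
  })

  centre <- colMeans(x)
  total_ss <- sum(sweep(x, 2, centre)^2)
  ve <- if (total_ss > 0) 1 - best$tot_withinss / total_ss else 1
  assignments <- rep(NA_integer_, length(keep))
  assignments[keep] <- best$cluster
  structure(list(
    k = k, centroids = best$centers, assignments = assignments,
    within_ss = best$withinss, total_ss = total_ss,
    variance_explained = ve, labels = NULL, complete = keep
  ), class = "stress_typology")
}

as_stress_matrix <- function(vectors) {
  if (is.matrix(vectors)) return(vectors)
  if (is.data.frame(vectors)) return(as.matrix(vectors))
  if (is.list(vectors)) {
    rows <- lapply(vectors, function(v) {
      if (is.list(v) && !is.null(v$stress)) v$stress else as.numeric(v)
    })
    return(do.call(rbind, rows))
  }
  stop("vectors must be a matrix, data.frame or list of stress vectors")
}

# k-means++ seeding: first centre uniform, then points with probability
# proportional to squared distance to the nearest chosen centre.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[idx[1], ])^2)
  for (j in seq_len(k - 1) + 1) {
    if (sum(d2) <= 0) {
      idx[j] <- sample.int(n, 1)
    } else {
      idx[j] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j], ])^2))
  }
  x[idx, , drop = FALSE]
}

# Lloyd iteration with empty-cluster re-seeding from the farthest point.
lloyd_kmeans <- function(x, centres, max_iter) {
  k <- nrow(centres)
  cluster <- integer(nrow(x))
  for (it in seq_len(max_iter)) {
    d <- point_centre_dist2(x, centres)
    new_cluster <- max.col(-d, ties.method = "first")
    # re-seed empty clusters: move the point farthest from its centroid
    # (drawn from clusters that can spare one) into the empty cluster;
    # assignments are patched, not recomputed, so fully duplicated data
    # cannot oscillate and the loop fills one empty cluster per pass
    repeat {
      sizes <- tabulate(new_cluster, k)
      empty <- which(sizes == 0)
      if (!length(empty)) break
      cand <- which(sizes[new_cluster] > 1)
      far <- cand[which.max(d[cbind(cand, new_cluster[cand])])]
      centres[empty[1], ] <- x[far, ]
      new_cluster[far] <- empty[1]
    }
    if (all(new_cluster == cluster) && it > 1) break
    cluster <- new_cluster
    for (j in seq_len(k)) {
      centres[j, ] <- colMeans(x[cluster == j, , drop = FALSE])
    }
  }
  d <- point_centre_dist2(x, centres)
  cluster <- max.col(-d, ties.method = "first")
  withinss <- vapply(seq_len(k), function(j) {
    sum(sweep(x[cluster == j, , drop = FALSE], 2, centres[j, ])^2)
  }, numeric(1))
  list(cluster = cluster, centers = centres, withinss = withinss,
       tot_withinss = sum(withinss))
}

point_centre_dist2 <- function(x, centres) {
  d <- matrix(0, nrow(x), nrow(centres))
  for (j in seq_len(nrow(centres))) {
    d[, j] <- rowSums(sweep(x, 2, centres[j, ])^2)
  }
  d
}

#' @export
print.stress_typology <- function(x, ...) {
  cat("<stress_typology> k = ", x$k, ", ", sum(x$complete),
      " seasons clustered, variance explained ",
      round(100 * x$variance_explained, 1), "%\n", sep = "")
  cents <- round(x$centroids, 3)
  rownames(cents) <- if (!is.null(x$labels)) x$labels else
    paste0("cluster", seq_len(x$k))
  print(cents)
  invisible(x)
}

#' Label typology clusters by severity and onset timing
#'
#' Orders clusters 0..k-1 by ascending total stress (sum over phases of
#' 1 - centroid element; ties broken earlier-onset-first) and attaches
#' labels `SW0..` (spring) or `WW0..` (winter) with a verbal descriptor:
#' `minimal waterlogging` when no phase centroid drops below the onset
#' threshold, otherwise severity (low/moderate/severe by total stress) plus
#' onset timing (early/mid/late by the earliest phase whose centroid falls
#' below the threshold).
#'
#' @param typology A fitted [fit_typology()] result.
#' @param maturity_class `"spring"` (labels SW*) or `"winter"` (WW*).
#' @param onset_threshold Centroid element below which a phase counts as
#'   stressed for the onset descriptor (default 0.95).
#' @return The typology with `labels`, `label_order` (severity rank per
#'   original cluster index), and `descriptors` filled in; `assignments`
#'   gain a `label` attribute-free companion via [typology_assignments()].
#' @export
label_clusters <- function(typology, maturity_class = c("spring", "winter"),
                           onset_threshold = 0.95) {
  maturity_class <- match.arg(maturity_class)
  prefix <- if (maturity_class == "spring") "SW" else "WW"
  cents <- typology$centroids
  total_stress <- rowSums(1 - cents)
  onset_phase <- apply(cents, 1, function(z) {
    w <- which(z < onset_threshold)
    if (length(w)) w[1] else Inf
  })
  ord <- order(total_stress, onset_phase)  # ties: earlier onset first
  rank <- match(seq_len(typology$k), ord) - 1  # severity index 0..k-1
  labels <- paste0(prefix, rank)

  descriptors <- vapply(seq_len(typology$k), function(j) {
    if (!is.finite(onset_phase[j])) return("minimal waterlogging")
    sev <- cut(total_stress[j], c(-Inf, 0.5, 1.5, Inf),
               labels = c("low", "moderate", "severe"))
    timing <- c("early-onset", "early-onset", "mid-season", "late-onset",
                "late-onset", "late-onset")[onset_phase[j]]
    paste(timing, sev, "waterlogging")
  }, character(1))

  typology$labels <- labels
  typology$label_order <- rank
  typology$descriptors <- descriptors
  typology$maturity_class <- maturity_class
  typology
}

#' Per-season pattern labels
#'
#' @param typology A labelled [label_clusters()] typology.
#' @return Character vector of pattern labels per season (`NA` for seasons
#'   excluded as incomplete).
#' @export
typology_assignments <- function(typology) {
  if (is.null(typology$labels)) stop("typology is not labelled yet")
  ifelse(is.na(typology$assignments), NA_character_,
         typology$labels[typology$assignments])
}

#' Stress-pattern recurrence frequencies
#'
#' Percentage of seasons falling in each stress pattern, per group (e.g.
#' scenario, sowing window or maturity class). Percentages within a group sum
#' to 100.
#'
#' @param labels Pattern label per season (see [typology_assignments()]);
#'   `NA` seasons are dropped.
#' @param group Grouping factor (same length), or `NULL` for a single group.
#' @return data.frame with columns `group`, `pattern`, `n`, `pct`.
#' @export
pattern_frequencies <- function(labels, group = NULL) {
  if (is.null(group)) group <- rep("all", length(labels))
  keep <- !is.na(labels)
  labels <- labels[keep]; group <- as.character(group)[keep]
  if (!length(labels)) {
    warning("no labelled seasons")
    return(data.frame(group = character(), pattern = character(),
                      n = integer(), pct = numeric()))
  }
  all_patterns <- sort(unique(labels))
  out <- do.call(rbind, lapply(split(labels, group), function(l) {
    n <- vapply(all_patterns, function(p) sum(l == p), integer(1))
    data.frame(pattern = all_patterns, n = n, pct = 100 * n / length(l))
  }))
  out$group <- rep(names(split(labels, group)),
                   each = length(all_patterns))
  rownames(out) <- NULL
  out[c("group", "pattern", "n", "pct")]
}
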