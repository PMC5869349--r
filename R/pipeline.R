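# Cohort-level orchestration: per-case similarity and margin analysis for
# every candidate plus their union (seg4), pairwise inter-candidate
# agreement, cohort summaries in mean +/- SD [median; min-max] form, and
# Wilcoxon comparisons between candidates. A case whose candidate is empty
# (reader missed the lesion) is excluded from that candidate's summaries,
# while the union is taken over whatever candidates are available.

similarity_fields <- c("dice", "jaccard", "hd_mm", "mda_mm",
                       "truth_volume_ml", "candidate_volume_ml",
                       "missed_volume_ml", "missed_percent")

#' Analyse a single segmentation case
#'
#' For each candidate and for their union (`seg4`): similarity report
#' against the truth, margin report, and ellipsoid-formula volume estimate
#' (omitted for the union, which is not a single drawn VOI). Empty
#' candidates are recorded as excluded and skipped.
#'
#' @param case A [segmentation_case()].
#' @param margins_mm Margins for the margin reports (mm), default 5 and 10.
#' @param union_name Name under which the union is reported.
#' @return A `case_result`: list with `case_id`, `similarity` (named list of
#'   similarity reports), `margin` (named list of margin reports),
#'   `ellipsoid_ml` (named vector, NA for the union), and `excluded`
#'   (names of empty candidates).
#' @export
analyze_case <- function(case, margins_mm = c(5, 10), union_name = "seg4") {
  if (!inherits(case, "segmentation_case"))
    stop("case must be a segmentation_case")
  nonempty <- Filter(function(m) sum(m$data) > 0, case$candidates)
  excluded <- setdiff(names(case$candidates), names(nonempty))
  if (length(nonempty) == 0)
    stop("case ", case$case_id, ": all candidates are empty")
  all_segs <- c(nonempty, setNames(list(union_masks(nonempty)), union_name))
  sim <- lapply(all_segs, function(m) similarity_report(case$truth, m))
  mar <- lapply(names(all_segs), function(nm)
    margin_report(case$truth, all_segs[[nm]], margins_mm,
                  candidate_name = nm))
  names(mar) <- names(all_segs)
  ell <- vapply(names(all_segs), function(nm) {
    if (nm == union_name) return(NA_real_)
    ellipsoid_volume_ml(max_extents(all_segs[[nm]]))
  }, numeric(1))
  structure(list(case_id = case$case_id, similarity = sim, margin = mar,
                 ellipsoid_ml = ell, excluded = excluded),
            class = "case_result")
}

#' Pairwise agreement between candidates of one case
#'
#' HD, MDA, Dice and Jaccard for every unordered pair of non-empty
#' candidates (no truth involved): the inter-reader / inter-method
#' agreement analysis.
#'
#' @param case A [segmentation_case()] with >= 2 candidates.
#' @return Data frame with one row per pair: `a`, `b`, `hd_mm`, `mda_mm`,
#'   `dice`, `jaccard`.
#' @export
pairwise_agreement <- function(case) {
  if (!inherits(case, "segmentation_case"))
    stop("case must be a segmentation_case")
  nonempty <- Filter(function(m) sum(m$data) > 0, case$candidates)
  nms <- names(nonempty)
  if (length(nms) < 2)
    return(data.frame(a = character(0), b = character(0),
                      hd_mm = numeric(0), mda_mm = numeric(0),
                      dice = numeric(0), jaccard = numeric(0)))
  pairs <- utils::combn(nms, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- nonempty[[pairs[1, j]]]; b <- nonempty[[pairs[2, j]]]
    data.frame(a = pairs[1, j], b = pairs[2, j],
               hd_mm = hausdorff_mm(a, b), mda_mm = mda_mm(a, b),
               dice = dice(a, b), jaccard = jaccard(a, b))
  })
  do.call(rbind, rows)
}

#' Analyse every case of a cohort
#'
#' @param cohort A `cohort` from [simulate_cohort()], or a plain list of
#'   [segmentation_case()] objects.
#' @param margins_mm Margins passed to [analyze_case()].
#' @return A `cohort_result`: list with `per_case` (named list of
#'   `case_result`), `agreement` (data frame with a `case_id` column), and
#'   `margins_mm`.
#' @export
analyze_cohort <- function(cohort, margins_mm = c(5, 10)) {
  cases <- if (inherits(cohort, "cohort")) cohort$cases else cohort
  per_case <- lapply(cases, analyze_case, margins_mm = margins_mm)
  names(per_case) <- vapply(per_case, `[[`, character(1), "case_id")
  agr <- lapply(cases, function(cs) {
    df <- pairwise_agreement(cs)
    if (nrow(df) > 0) cbind(case_id = cs$case_id, df) else NULL
  })
  agr <- do.call(rbind, Filter(Negate(is.null), agr))
  structure(list(per_case = per_case, agreement = agr,
                 margins_mm = margins_mm),
            class = "cohort_result")
}

# per-candidate metric vector across cases; NA when candidate excluded
metric_values <- function(result, candidate, metric) {
  vapply(result$per_case, function(cr) {
    if (!candidate %in% names(cr$similarity)) return(NA_real_)
    if (metric == "ellipsoid_ml") return(cr$ellipsoid_ml[[candidate]])
    if (metric == "min_coverage_margin_mm")
      return(cr$margin[[candidate]]$min_coverage_margin_mm)
    mm <- regmatches(metric, regexec("^(expanded|missed)_(volume_ml|percent)_([0-9.]+)mm$", metric))[[1]]
    if (length(mm) == 4) {
      rep <- cr$margin[[candidate]]
      i <- which(abs(rep$margins_mm - as.numeric(mm[4])) < 1e-9)
      if (length(i) != 1) return(NA_real_)
      fld <- if (mm[2] == "expanded") "expanded_volume_ml"
             else if (mm[3] == "volume_ml") "missed_volume_ml" else "missed_percent"
      return(rep[[fld]][i])
    }
    cr$similarity[[candidate]][[metric]]
  }, numeric(1))
}

five_number <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0)
    return(data.frame(n = 0L, mean = NA_real_, sd = NA_real_,
                      median = NA_real_, min = NA_real_, max = NA_real_))
  data.frame(n = length(x), mean = mean(x),
             sd = if (length(x) > 1) sd(x) else 0,
             median = median(x), min = min(x), max = max(x))
}

#' Summarise a cohort analysis
#'
#' Produces the three standard summary tables, each in long form with
#' mean, SD, median, min, max and n per (candidate, metric):
#' `similarity` (volumes, missed volume, HD, MDA, Dice, Jaccard, ellipsoid
#' estimate, per candidate vs truth), `agreement` (pairwise candidate
#' metrics), and `margins` (expanded and residual missed volumes per safety
#' margin plus the minimum coverage margin). Summaries only include cases
#' where the candidate is non-empty.
#'
#' @param result A `cohort_result` from [analyze_cohort()].
#' @return List of data frames `similarity`, `agreement`, `margins`.
#' @export
summarize_cohort <- function(result) {
  if (!inherits(result, "cohort_result"))
    stop("result must be a cohort_result")
  cands <- unique(unlist(lapply(result$per_case,
                                function(cr) names(cr$similarity))))
  sim_metrics <- c("truth_volume_ml", "ellipsoid_ml", "candidate_volume_ml",
                   "missed_volume_ml", "missed_percent", "hd_mm", "mda_mm",
                   "dice", "jaccard")
  sim <- do.call(rbind, lapply(cands, function(cd)
    do.call(rbind, lapply(sim_metrics, function(mt)
      cbind(candidate = cd, metric = mt,
            five_number(metric_values(result, cd, mt)))))))
  mar_metrics <- c(
    unlist(lapply(result$margins_mm, function(m)
      sprintf(c("expanded_volume_ml_%gmm", "missed_volume_ml_%gmm",
                "missed_percent_%gmm"), m))),
    "min_coverage_margin_mm")
  mar <- do.call(rbind, lapply(cands, function(cd)
    do.call(rbind, lapply(mar_metrics, function(mt)
      cbind(candidate = cd, metric = mt,
            five_number(metric_values(result, cd, mt)))))))
  agr <- NULL
  if (!is.null(result$agreement) && nrow(result$agreement) > 0) {
    key <- paste(result$agreement$a, "vs", result$agreement$b)
    agr <- do.call(rbind, lapply(unique(key), function(k) {
      sub <- result$agreement[key == k, ]
      do.call(rbind, lapply(c("hd_mm", "mda_mm", "dice", "jaccard"),
                            function(mt)
        cbind(comparison = k, metric = mt, five_number(sub[[mt]]))))
    }))
  }
  list(similarity = sim, agreement = agr, margins = mar)
}

#' Wilcoxon comparison of two candidates on one metric
#'
#' Paired Wilcoxon signed-rank (candidate vs candidate across cases, or a
#' candidate's metric vs the truth-derived metric) or unpaired Wilcoxon
#' rank-sum, two-sided. The exact distribution is used for n <= 20 without
#' ties (zero differences dropped first, the classical signed-rank rule);
#' otherwise the normal approximation with tie correction. Comparisons with
#' fewer than 5 observations are still computed but flagged as
#' underpowered; all-zero differences return p = 1 with a flag.
#'
#' @param result A `cohort_result`.
#' @param metric Metric name as in the summary tables (e.g.
#'   `"missed_percent"`, `"min_coverage_margin_mm"`).
#' @param pair Character length-2: the candidates to compare.
#' @param paired Use the paired signed-rank test (default TRUE; cases where
#'   either member is missing are dropped).
#' @return List with `comparison`, `metric`, `statistic`, `p_value`, `n`,
#'   `paired`, `method`, `flags`.
#' @export
compare_candidates <- function(result, metric, pair, paired = TRUE) {
  if (length(pair) != 2) stop("pair must name two candidates")
  x <- metric_values(result, pair[1], metric)
  y <- metric_values(result, pair[2], metric)
  if (paired) {
    keep <- !is.na(x) & !is.na(y)
    w <- wilcoxon_test(x[keep], y[keep], paired = TRUE)
  } else {
    w <- wilcoxon_test(x[!is.na(x)], y[!is.na(y)], paired = FALSE)
  }
  c(list(comparison = paste(pair[1], "vs", pair[2]), metric = metric), w)
}

# Two-sided Wilcoxon wrapper around stats::wilcox.test with explicit
# zero-difference handling and exact/approximate selection.
wilcoxon_test <- function(x, y, paired = TRUE) {
  flags <- character(0)
  if (paired) {
    d <- x - y
    d <- d[d != 0]
    if (length(d) == 0)
      return(list(statistic = NA_real_, p_value = 1, n = 0L, paired = TRUE,
                  method = "signed-rank (all differences zero)",
                  flags = "all_zero"))
    n <- length(d)
    if (n < 5) flags <- c(flags, "underpowered")
    exact <- n <= 20 && !any(duplicated(abs(d)))
    ht <- suppressWarnings(wilcox.test(d, exact = exact, correct = !exact))
    method <- if (exact) "signed-rank exact" else "signed-rank normal approx"
  } else {
    n <- min(length(x), length(y))
    if (n < 5) flags <- c(flags, "underpowered")
    exact <- length(x) <= 20 && length(y) <= 20 &&
      !any(duplicated(c(x, y)))
    ht <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                       correct = !exact))
    method <- if (exact) "rank-sum exact" else "rank-sum normal approx"
    n <- length(x) + length(y)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n = as.integer(n), paired = paired, method = method, flags = flags)
}

#' Write cohort analysis tables to disk
#'
#' Emits `similarity.csv`, `agreement.csv` and `margins.csv` (the long-form
#' summary tables from [summarize_cohort()]), a per-case
#' `per_case_similarity.csv`, a structured `per_case.json` metric dump, and
#' `tests.json` when comparisons are given.
#'
#' @param result A `cohort_result`.
#' @param dir Output directory (created if needed).
#' @param tests Optional list of results from [compare_candidates()].
#' @return `dir`, invisibly.
#' @export
write_cohort_results <- function(result, dir, tests = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- summarize_cohort(result)
  write.csv(s$similarity, file.path(dir, "similarity.csv"),
            row.names = FALSE)
  if (!is.null(s$agreement))
    write.csv(s$agreement, file.path(dir, "agreement.csv"),
              row.names = FALSE)
  write.csv(s$margins, file.path(dir, "margins.csv"), row.names = FALSE)
  rows <- lapply(result$per_case, function(cr) {
    do.call(rbind, lapply(names(cr$similarity), function(cd) {
      sr <- cr$similarity[[cd]]
      data.frame(case_id = cr$case_id, candidate = cd,
                 as.data.frame(sr[similarity_fields]),
                 ellipsoid_ml = cr$ellipsoid_ml[[cd]],
                 min_coverage_margin_mm =
                   cr$margin[[cd]]$min_coverage_margin_mm)
    }))
  })
  write.csv(do.call(rbind, rows), file.path(dir, "per_case_similarity.csv"),
            row.names = FALSE)
  dump <- lapply(result$per_case, function(cr) list(
    similarity = lapply(cr$similarity, unclass),
    margins = lapply(cr$margin, unclass),
    ellipsoid_ml = as.list(cr$ellipsoid_ml),
    excluded = cr$excluded))
  jsonlite::write_json(dump, file.path(dir, "per_case.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(tests))
    jsonlite::write_json(tests, file.path(dir, "tests.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
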