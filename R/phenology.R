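#' Accumulated thermal time between two dates
#'
#' Thermal time standardizes phenology for temperature: it is the sum of
#' daily mean temperatures, `(tmin + tmax) / 2`, over the days in
#' `(t0, t]`, with negative daily means clamped to zero (base temperature
#' 0 degC). `t0` is conventionally the date of ear emergence (GS55).
#'
#' @param temps data.frame with columns `date` (Date or ISO-8601
#'   character), `tmin`, `tmax`.
#' @param t0 start date (excluded from the sum).
#' @param t end date (included); must satisfy `t >= t0`.
#' @return thermal time in day degC; 0 when `t == t0`.
#' @examples
#' temps <- data.frame(date = as.Date("2017-06-01") + 0:4,
#'                     tmin = 20, tmax = 20)
#' compute_thermal_time(temps, as.Date("2017-05-31"), as.Date("2017-06-05"))
#' @export
compute_thermal_time <- function(temps, t0, t) {
  t0 <- as.Date(t0); t <- as.Date(t)
  if (t < t0) stop("`t` must not precede `t0`", call. = FALSE)
  if (t == t0) return(0)
  if (any(temps$tmax < temps$tmin))
    stop("temperature series has tmax < tmin", call. = FALSE)
  dates <- as.Date(temps$date)
  wanted <- seq(t0 + 1, t, by = "day")
  idx <- match(wanted, dates)
  if (anyNA(idx))
    stop("temperature series is missing days: ",
         paste(format(wanted[is.na(idx)]), collapse = ", "), call. = FALSE)
  sum(pmax(0, (temps$tmin[idx] + temps$tmax[idx]) / 2))
}

.check_timecourse <- function(tc) {
  if (is.null(tc) || nrow(tc) == 0)
    stop("empty senescence time course", call. = FALSE)
  if (!all(c("thermal_time", "score") %in% names(tc)))
    stop("time course needs columns `thermal_time` and `score`", call. = FALSE)
  tc[order(tc$thermal_time), , drop = FALSE]
}

#' First recorded crossing of a senescence score threshold
#'
#' Onset and termination of senescence are defined at recorded
#' observations, not interpolated: the thermal time of the first
#' observation whose score is strictly above the threshold (10 for onset,
#' 90 for termination). On a step-5 scale this means scores of 15 / 95 or
#' more trigger.
#'
#' @param tc time course data.frame with `thermal_time` and `score`.
#' @param threshold score threshold (conventionally 10 or 90).
#' @return thermal time in day degC, or `NA_real_` if the score never
#'   exceeds the threshold.
#' @export
find_crossing <- function(tc, threshold) {
  tc <- .check_timecourse(tc)
  i <- which(tc$score > threshold)
  if (length(i) == 0) return(NA_real_)
  tc$thermal_time[i[1]]
}

#' Thermal time to a target senescence score by linear interpolation
#'
#' Senescence is assumed to progress linearly between scoring points. If
#' some observation records the target exactly, the thermal time of the
#' first such observation is returned. Otherwise the first upward crossing
#' is located (first observation above the target, bracketed by the last
#' earlier observation below it) and the time interpolated. If the first
#' observation already exceeds the target the crossing predates scoring
#' and the first observation's thermal time is returned as the earliest
#' bound.
#'
#' @param tc time course data.frame with `thermal_time` and `score`.
#' @param target target score in (0, 100].
#' @return thermal time in day degC, or `NA_real_` if the target is never
#'   reached.
#' @examples
#' tc <- data.frame(thermal_time = c(300, 340), score = c(60, 80))
#' interpolate_tt_score(tc, 70)  # 320
#' @export
interpolate_tt_score <- function(tc, target) {
  if (!is.finite(target) || target <= 0 || target > 100)
    stop("`target` must lie in (0, 100]", call. = FALSE)
  tc <- .check_timecourse(tc)
  hit <- which(tc$score == target)
  if (length(hit) > 0) return(tc$thermal_time[hit[1]])
  above <- which(tc$score > target)
  if (length(above) == 0) return(NA_real_)
  i <- above[1]
  if (i == 1) return(tc$thermal_time[1])
  below <- which(tc$score[seq_len(i - 1)] < target)
  j <- below[length(below)]
  s_j <- tc$score[j]; s_i <- tc$score[i]
  tc$thermal_time[j] +
    (target - s_j) / (s_i - s_j) * (tc$thermal_time[i] - tc$thermal_time[j])
}

#' Derive the senescence metric panel from one score time course
#'
#' Computes the metrics used to quantify and compare senescence profiles:
#' mean of recorded scores, onset and termination (first recorded score
#' above 10 / 90), durations from ear emergence and from onset to terminal
#' senescence, and the interpolated thermal times TT30 ... TT90 to scores
#' 30 through 90. Undefined quantities (threshold or target never reached)
#' propagate as `NA`, never as zeros.
#'
#' @param tc time course data.frame with `thermal_time` and `score`
#'   (thermal time measured from ear emergence).
#' @return object of class `senescence_metrics`: list with
#'   `mean_senescence`, `onset`, `termination`, `duration_from_ee`,
#'   `duration_from_onset` and `tt_scores` (named vector TT30..TT90).
#' @export
derive_metrics <- function(tc) {
  tc <- .check_timecourse(tc)
  if (nrow(tc) < 2)
    stop("need at least two observations to derive metrics", call. = FALSE)
  onset <- find_crossing(tc, 10)
  term <- find_crossing(tc, 90)
  targets <- seq(30, 90, by = 10)
  tts <- vapply(targets, function(s) interpolate_tt_score(tc, s), numeric(1))
  names(tts) <- paste0("TT", targets)
  out <- list(mean_senescence = mean(tc$score),
              onset = onset,
              termination = term,
              duration_from_ee = term,
              duration_from_onset = term - onset,
              tt_scores = tts)
  class(out) <- "senescence_metrics"
  out
}

#' @export
print.senescence_metrics <- function(x, ...) {
  cat(sprintf("Senescence metrics: mean %.1f, onset %s, termination %s day degC\n",
              x$mean_senescence, format(round(x$onset, 1)),
              format(round(x$termination, 1))))
  cat("  ", paste(names(x$tt_scores), round(x$tt_scores, 1),
                  sep = "=", collapse = "  "), "\n")
  invisible(x)
}

# fetch one metric by name ("mean_senescence", "onset", ..., "tt70")
.metric_value <- function(m, name) {
  lname <- tolower(name)
  if (lname %in% names(m)) return(m[[lname]])
  if (grepl("^tt[0-9]+$", lname)) {
    key <- toupper(lname)
    if (key %in% names(m$tt_scores)) return(unname(m$tt_scores[key]))
  }
  stop("unknown senescence metric: ", name, call. = FALSE)
}

#' Classify a RIL as staygreen or non-staygreen relative to its parents
#'
#' Each metric in the rule votes for the parent it is closer to; the line
#' is classified when one side reaches the vote threshold and the other
#' receives no more votes, otherwise it is `ambiguous`. This mirrors
#' classification of lines whose metrics fall between parental values by
#' concordance across metrics.
#'
#' @param metrics [derive_metrics()] result for the line.
#' @param wt_parent_metrics,sg_parent_metrics parental metric panels
#'   (wild-type / staygreen parent).
#' @param rule list with `metrics` (character vector of metric names, e.g.
#'   `c("mean_senescence", "duration_from_ee", "tt70")`) and `min_votes`
#'   (votes required to call a class).
#' @return object of class `ril_classification`: list with `class`
#'   (`"staygreen"`, `"non_staygreen"` or `"ambiguous"`), `votes`, and an
#'   `evidence` data.frame of per-metric comparisons.
#' @export
classify_ril <- function(metrics, wt_parent_metrics, sg_parent_metrics,
                         rule = list(metrics = c("mean_senescence",
                                                 "duration_from_ee", "tt70"),
                                     min_votes = 2)) {
  ev <- lapply(rule$metrics, function(nm) {
    v <- .metric_value(metrics, nm)
    vw <- .metric_value(wt_parent_metrics, nm)
    vs <- .metric_value(sg_parent_metrics, nm)
    if (is.na(vw) || is.na(vs))
      stop("parental metric `", nm, "` is missing", call. = FALSE)
    vote <- if (is.na(v) || abs(v - vw) == abs(v - vs)) NA_character_
            else if (abs(v - vs) < abs(v - vw)) "staygreen" else "non_staygreen"
    data.frame(metric = nm, value = v, wt = vw, sg = vs, vote = vote,
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, ev)
  n_sg <- sum(ev$vote == "staygreen", na.rm = TRUE)
  n_nsg <- sum(ev$vote == "non_staygreen", na.rm = TRUE)
  cls <- if (n_sg >= rule$min_votes && n_sg > n_nsg) "staygreen"
         else if (n_nsg >= rule$min_votes && n_nsg > n_sg) "non_staygreen"
         else "ambiguous"
  out <- list(class = cls, votes = c(staygreen = n_sg, non_staygreen = n_nsg),
              evidence = ev)
  class(out) <- "ril_classification"
  out
}

#' @export
print.ril_classification <- function(x, ...) {
  cat(sprintf("RIL classification: %s (votes SG %d / NSG %d)\n",
              x$class, x$votes["staygreen"], x$votes["non_staygreen"]))
  invisible(x)
}

#' Select sequencing bulks from multi-year classifications
#'
#' A line enters a bulk only when classified identically (and not
#' ambiguously) in at least `min_years` seasons and never in the opposite
#' class. When more lines are eligible than a bulk can hold, lines with
#' the strongest mean TT70 deviation from the mid-parent value are kept --
#' a deterministic tie-break favouring phenotypic extremes.
#'
#' @param classifications data.frame with columns `ril`, `year`, `class`
#'   (`staygreen` / `non_staygreen` / `ambiguous`) and `tt70`.
#' @param min_years minimum concordant seasons.
#' @param bulk_caps named vector `c(sg = , nsg = )` of maximum bulk sizes.
#' @param midparent_tt70 mid-parent TT70; defaults to the mean TT70 of all
#'   classified lines when unspecified.
#' @param min_eligible floor below which a warning status is raised.
#' @return list with `sg` and `nsg` (selected RIL ids), `eligible`
#'   (per-line summary table) and `status` (`"ok"` or `"warning: ..."`).
#' @export
select_bulks <- function(classifications, min_years = 2,
                         bulk_caps = c(sg = 17, nsg = 17),
                         midparent_tt70 = NULL, min_eligible = 5) {
  stopifnot(all(c("ril", "year", "class", "tt70") %in% names(classifications)))
  if (is.null(midparent_tt70))
    midparent_tt70 <- mean(classifications$tt70, na.rm = TRUE)
  per <- lapply(split(classifications, classifications$ril), function(d) {
    data.frame(ril = d$ril[1],
               n_sg = sum(d$class == "staygreen"),
               n_nsg = sum(d$class == "non_staygreen"),
               mean_tt70 = mean(d$tt70, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  per$deviation <- abs(per$mean_tt70 - midparent_tt70)
  per$eligible <- ifelse(per$n_sg >= min_years & per$n_nsg == 0, "sg",
                  ifelse(per$n_nsg >= min_years & per$n_sg == 0, "nsg", "no"))
  pick <- function(side, cap) {
    cand <- per[per$eligible == side, , drop = FALSE]
    cand <- cand[order(-cand$deviation, cand$ril), , drop = FALSE]
    utils::head(cand$ril, cap)
  }
  sg <- pick("sg", bulk_caps[["sg"]])
  nsg <- pick("nsg", bulk_caps[["nsg"]])
  status <- "ok"
  if (length(sg) < min_eligible || length(nsg) < min_eligible) {
    status <- sprintf("warning: fewer eligible RILs than floor (%d SG, %d NSG, floor %d)",
                      length(sg), length(nsg), min_eligible)
    warning(status, call. = FALSE)
  }
  list(sg = sg, nsg = nsg, eligible = per, status = status)
}

#' Grain moisture content from fresh and dry weights
#'
#' Moisture content is the water fraction of fresh weight,
#' `100 (fresh - dry) / fresh` percent, which declines toward grain
#' maturity. The ratio dry/fresh is the dry-matter fraction, not moisture;
#' `literal = TRUE` returns `100 dry / fresh` for comparison with sources
#' that phrase the computation that way.
#'
#' @param fresh_mg,dry_mg fresh and dry grain weights (any common unit);
#'   must satisfy `fresh >= dry > 0`.
#' @param literal return the dry-matter percentage instead.
#' @return moisture (or dry-matter) content in percent, vectorized.
#' @examples
#' moisture_percent(1000, 550)  # 45
#' @export
moisture_percent <- function(fresh_mg, dry_mg, literal = FALSE) {
  if (any(dry_mg <= 0)) stop("dry weight must be positive", call. = FALSE)
  if (any(dry_mg > fresh_mg))
    stop("dry weight exceeds fresh weight", call. = FALSE)
  if (literal) 100 * dry_mg / fresh_mg else 100 * (fresh_mg - dry_mg) / fresh_mg
}

#' Compare genotype groups at a single time point
#'
#' Fixed-effects comparison of a measurement (e.g. grain moisture or a
#' senescence score) across genotype groups at one time point: an overall
#' one-way F-test plus pairwise Welch two-sample t-tests. Degenerate
#' groups with zero variance and equal means return p = 1 by convention.
#'
#' @param values numeric measurements.
#' @param group group labels (coerced to factor), >= 2 groups with >= 2
#'   values each.
#' @return list with `f_p` (overall F-test p), `means` (named group
#'   means) and `pairwise` (data.frame `g1`, `g2`, `p`).
#' @export
timepoint_group_test <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2)
    stop("need at least two groups", call. = FALSE)
  if (any(table(group) < 2))
    stop("need at least two values per group", call. = FALSE)
  means <- tapply(values, group, mean)
  welch <- function(x, y) {
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(if (mean(x) == mean(y)) 1 else 0)
    stats::t.test(x, y)$p.value
  }
  if (stats::sd(values) == 0) {
    f_p <- 1
  } else {
    f_p <- stats::anova(stats::lm(values ~ group))[["Pr(>F)"]][1]
  }
  pairs <- utils::combn(levels(group), 2)
  pw <- data.frame(g1 = pairs[1, ], g2 = pairs[2, ],
                   p = apply(pairs, 2, function(pr)
                     welch(values[group == pr[1]], values[group == pr[2]])),
                   stringsAsFactors = FALSE)
  list(f_p = f_p, means = means, pairwise = pw)
}
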