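## Regulatory-redundancy analyses: GHS hazard prevalence, inter-guideline
## agreement of the 2,000 mg/kg classification, the 28-day-NOAEL contingency
## rule for acute toxicity (with NPV/PPV and the avoidable-study count), the
## Taylor-style constraints with 28-to-90-day predictivity, and the factor-3
## derived no-effect-level check.

#' Hazard prevalence summary
#'
#' Counts per GHS oral/aspiration hazard and the conclusive-positive
#' percentage, `positive / (positive + negative) * 100` rounded to one
#' decimal ("negative" meaning conclusive-but-not-classified). With no
#' conclusive records the percentage is undefined and reported as `NA`.
#'
#' @param hazards A hazard table (see [as_hazard_table()]).
#' @return Data frame: `hazard`, the four status counts, `pct_positive`.
#' @export
hazard_prevalence <- function(hazards) {
  hazards <- as_hazard_table(hazards)
  present <- intersect(hazard_codes(), names(hazards))
  rows <- lapply(present, function(h) {
    s <- hazards[[h]]
    pos <- sum(s == "positive"); neg <- sum(s == "negative")
    data.frame(hazard = h, positive = pos, negative = neg,
               data_lacking = sum(s == "data_lacking"),
               inconclusive = sum(s == "inconclusive"),
               pct_positive = if (pos + neg > 0)
                 round(100 * pos / (pos + neg), 1L) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Non-toxic complement of the oral-hazard percentages
#'
#' The percentage of substances carrying none of the named oral hazards,
#' computed as 100 minus the sum of their one-decimal conclusive-positive
#' percentages (the convention under which a 0.6 + 3.9 + 18.7 + 0.4 split
#' leaves 76.4).
#'
#' @param prevalence Output of [hazard_prevalence()].
#' @param hazards Hazard codes to subtract (default the four oral-intake
#'   hazards H300--H303).
#' @return Percentage, one decimal.
#' @export
nontoxic_complement <- function(prevalence,
                                hazards = c("H300", "H301", "H302", "H303")) {
  rows <- prevalence[prevalence$hazard %in% hazards, ]
  if (anyNA(rows$pct_positive))
    stop("undefined hazard percentage among ",
         paste(hazards, collapse = ", "), call. = FALSE)
  round(100 - sum(rows$pct_positive), 1L)
}

#' Inter-guideline agreement of the toxicant classification
#'
#' Two guidelines agree on a substance when its per-guideline aggregated
#' LD50 values fall on the same side of the threshold (both below 2,000 or
#' both at/above). Off-diagonal cells cover substances with at least one
#' study under each guideline; the diagonal measures self-consistency over
#' substances with two or more studies under that guideline (all its
#' study-level values must classify identically). Percentages come with the
#' substance counts they are based on.
#'
#' @param studies A study table of acute studies.
#' @param threshold Classification threshold in mg/kg b.w.
#' @param guidelines Guideline codes to compare.
#' @return An `agreement_matrix`: list of symmetric `percent` and `n`
#'   matrices.
#' @export
guideline_agreement <- function(studies, threshold = 2000,
                                guidelines = c("TG401", "TG420", "TG423",
                                               "TG425")) {
  studies <- as_study_table(studies)
  studies <- studies[studies$endpoint == "acute_oral" &
                       studies$guideline %in% guidelines, , drop = FALSE]
  k <- length(guidelines)
  pct <- matrix(NA_real_, k, k, dimnames = list(guidelines, guidelines))
  n <- matrix(0L, k, k, dimnames = list(guidelines, guidelines))
  ## per-(substance, guideline) aggregated class
  agg <- stats::aggregate(value ~ substance_id + guideline, data = studies,
                          FUN = mean)
  agg$class <- agg$value < threshold
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      a <- guidelines[i]; b <- guidelines[j]
      if (i == j) {
        per <- split(studies$value[studies$guideline == a],
                     studies$substance_id[studies$guideline == a])
        per <- per[lengths(per) >= 2L]
        n[i, j] <- length(per)
        if (length(per))
          pct[i, j] <- round(100 * mean(vapply(per, function(v)
            length(unique(v < threshold)) == 1L, logical(1))), 0L)
      } else if (i < j) {
        ca <- agg[agg$guideline == a, c("substance_id", "class")]
        cb <- agg[agg$guideline == b, c("substance_id", "class")]
        both <- merge(ca, cb, by = "substance_id")
        n[i, j] <- n[j, i] <- nrow(both)
        if (nrow(both))
          pct[i, j] <- pct[j, i] <-
            round(100 * mean(both$class.x == both$class.y), 0L)
      }
    }
  }
  structure(list(percent = pct, n = n, threshold = threshold),
            class = "agreement_matrix")
}

#' @export
print.agreement_matrix <- function(x, ...) {
  cat(sprintf("Guideline agreement at %g mg/kg b.w. (%% , n):\n", x$threshold))
  m <- matrix(sprintf("%s%% (%d)", ifelse(is.na(x$percent), "-",
                                          format(x$percent)), x$n),
              nrow = nrow(x$percent), dimnames = dimnames(x$percent))
  print(m, quote = FALSE)
  invisible(x)
}

#' Contingency analysis of the 28-day-NOAEL rule for acute toxicity
#'
#' Cross-tabulates matched substance-level 28-day NOAEL and acute LD50
#' values against the rule "NOAEL above 200 mg/kg predicts LD50 at or above
#' 2,000 mg/kg": rows are NOAEL at/below vs above the threshold, columns
#' LD50 below vs at/above 2,000. The negative predictive value is the
#' fraction of the NOAEL-above row with non-toxic LD50; the positive
#' predictive value the fraction of the NOAEL-at/below row with toxic LD50;
#' the avoidable-study count is the (NOAEL above, LD50 non-toxic) cell --
#' the acute studies the rule would have made unnecessary.
#'
#' @param noael_28d,ld50 Matched numeric vectors of substance-level values
#'   (mg/kg b.w.).
#' @param noael_threshold,ld50_threshold Rule thresholds.
#' @return A `bulgheroni_result`: list with `table` (2x2 integer matrix),
#'   `npv`, `ppv` (percent, one decimal, `NA` when undefined),
#'   `avoidable_count` and `n`.
#' @export
bulgheroni_from_pairs <- function(noael_28d, ld50, noael_threshold = 200,
                                  ld50_threshold = 2000) {
  stopifnot(length(noael_28d) == length(ld50))
  ok <- !is.na(noael_28d) & !is.na(ld50)
  noael_28d <- noael_28d[ok]; ld50 <- ld50[ok]
  if (!length(ld50))
    stop("no matched NOAEL/LD50 pairs", call. = FALSE)
  low_noael <- noael_28d <= noael_threshold
  toxic <- ld50 < ld50_threshold
  tab <- matrix(c(sum(low_noael & toxic), sum(low_noael & !toxic),
                  sum(!low_noael & toxic), sum(!low_noael & !toxic)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(
                  c(sprintf("NOAEL<=%g", noael_threshold),
                    sprintf("NOAEL>%g", noael_threshold)),
                  c(sprintf("LD50<%g", ld50_threshold),
                    sprintf("LD50>=%g", ld50_threshold))))
  pos_row <- sum(tab[1L, ]); neg_row <- sum(tab[2L, ])
  structure(list(
    table = tab,
    npv = if (neg_row > 0) round(100 * tab[2L, 2L] / neg_row, 1L) else
      NA_real_,
    ppv = if (pos_row > 0) round(100 * tab[1L, 1L] / pos_row, 1L) else
      NA_real_,
    avoidable_count = unname(tab[2L, 2L]),
    n = sum(tab)), class = "bulgheroni_result")
}

#' @export
print.bulgheroni_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("NPV %s%%  PPV %s%%  avoidable acute studies: %d  (n = %d)\n",
              format(x$npv), format(x$ppv), x$avoidable_count, x$n))
  invisible(x)
}

#' @rdname bulgheroni_from_pairs
#' @param studies A study table holding acute and 28-day rows.
#' @param study_scope `"all"` uses every acute study (including read-across
#'   and non-key records); `"key_only"` restricts the LD50 aggregation to
#'   experimental key studies.
#' @export
bulgheroni_table <- function(studies, noael_threshold = 200,
                             ld50_threshold = 2000,
                             study_scope = c("all", "key_only")) {
  study_scope <- match.arg(study_scope)
  studies <- as_study_table(studies)
  acute_filter <- if (study_scope == "key_only")
    function(df) df$key_study & !df$read_across else NULL
  ld50 <- aggregate_endpoints(studies, filter = acute_filter,
                              endpoint = "acute_oral")
  noael <- aggregate_endpoints(studies, endpoint = "repeated_28d")
  both <- merge(ld50[c("substance_id", "mean_value")],
                noael[c("substance_id", "mean_value")],
                by = "substance_id", suffixes = c("_ld50", "_noael"))
  if (!nrow(both))
    stop("no substances with both an acute LD50 and a 28-day NOAEL",
         call. = FALSE)
  bulgheroni_from_pairs(both$mean_value_noael, both$mean_value_ld50,
                        noael_threshold, ld50_threshold)
}

#' Matched substance-level 28-day / 90-day NOAEL pairs
#'
#' Aggregates both repeated-dose endpoints per substance and joins them.
#'
#' @param studies A study table.
#' @param filter Optional selection predicate passed to aggregation.
#' @return Data frame `substance_id`, `noael_28d`, `noael_90d`.
#' @export
matched_noael_pairs <- function(studies, filter = NULL) {
  studies <- as_study_table(studies)
  a28 <- aggregate_endpoints(studies, filter = filter,
                             endpoint = "repeated_28d")
  a90 <- aggregate_endpoints(studies, filter = filter,
                             endpoint = "repeated_90d")
  out <- merge(a28[c("substance_id", "mean_value")],
               a90[c("substance_id", "mean_value")], by = "substance_id")
  names(out) <- c("substance_id", "noael_28d", "noael_90d")
  out
}

#' Taylor-style constraint filter
#'
#' Approximates the published redundancy constraints on machine-readable
#' fields: a substance qualifies when it has at least one 28-day study with
#' Klimisch score 1 or 2 and carries no positive flag among the tracked GHS
#' H3xx hazards. The additional high-dose condition (28-day NOAEL at or
#' above 1,000 mg/kg) is returned as a separate boolean, not applied as a
#' filter, so the predictivity split can use it directly.
#'
#' @param studies A study table.
#' @param hazards A hazard table covering the same substances.
#' @param noael_high Threshold for the high-NOAEL boolean (mg/kg b.w.).
#' @return Data frame `substance_id`, `noael_28d`, `high_28d` for the
#'   qualifying substances.
#' @export
taylor_filter <- function(studies, hazards, noael_high = 1000) {
  studies <- as_study_table(studies)
  hazards <- as_hazard_table(hazards)
  rel <- studies[studies$endpoint == "repeated_28d" &
                   studies$klimisch <= 2L, , drop = FALSE]
  if (!nrow(rel))
    return(data.frame(substance_id = character(), noael_28d = numeric(),
                      high_28d = logical(), stringsAsFactors = FALSE))
  agg <- aggregate_endpoints(rel, endpoint = "repeated_28d")
  present <- intersect(hazard_codes(), names(hazards))
  any_pos <- apply(hazards[present] == "positive", 1L, any)
  clean <- hazards$substance_id[!any_pos]
  agg <- agg[agg$substance_id %in% clean, , drop = FALSE]
  data.frame(substance_id = agg$substance_id, noael_28d = agg$mean_value,
             high_28d = agg$mean_value >= noael_high,
             stringsAsFactors = FALSE)
}

#' 28-day to 90-day NOAEL predictivity
#'
#' Among matched pairs whose 28-day NOAEL is at or above the threshold, the
#' percentage whose 90-day NOAEL is also at or above it -- reported for the
#' full pair set and, when a constraint subset is supplied, for that subset.
#'
#' @param pairs Data frame from [matched_noael_pairs()].
#' @param threshold NOAEL threshold in mg/kg b.w. (strict `>=` on both
#'   sides).
#' @param constrained Optional character vector of substance ids meeting the
#'   Taylor-style constraints.
#' @return Data frame with rows `full` (and `constrained`): `n_high28`,
#'   `pct_high90_given_high28` (`NA` when no qualifying pair).
#' @export
taylor_predictivity <- function(pairs, threshold = 1000, constrained = NULL) {
  one <- function(df) {
    hi28 <- df$noael_28d >= threshold
    n <- sum(hi28)
    data.frame(n_high28 = n,
               pct_high90_given_high28 = if (n > 0)
                 round(100 * mean(df$noael_90d[hi28] >= threshold), 1L) else
                   NA_real_)
  }
  out <- cbind(set = "full", one(pairs))
  if (!is.null(constrained))
    out <- rbind(out, cbind(set = "constrained",
                            one(pairs[pairs$substance_id %in% constrained, ,
                                      drop = FALSE])))
  out
}

#' Factor-3 derived no-effect-level check
#'
#' Tests the pragmatic extrapolation of a 90-day DNEL from a 28-day NOAEL
#' with an assessment factor of 3: a pair is below the limit when the
#' 90-day NOAEL is strictly less than one third of the 28-day NOAEL (a pair
#' at exactly one third counts as within).
#'
#' @param pairs Data frame from [matched_noael_pairs()] (key-study pairs).
#' @return List `n_pairs`, `n_below_one_third`, `pct_within` (one decimal).
#' @export
factor3_check <- function(pairs) {
  if (!nrow(pairs)) stop("no matched NOAEL pairs", call. = FALSE)
  below <- pairs$noael_90d < pairs$noael_28d / 3
  list(n_pairs = nrow(pairs), n_below_one_third = sum(below),
       pct_within = round(100 * (nrow(pairs) - sum(below)) / nrow(pairs), 1L))
}
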