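#' Default K = 14 neuropsychological battery definition
#'
#' The battery reduces 16 raw subtest columns to 14 oriented subtests:
#' MMSE, Mattis, Corsi block-tapping (mean of the direct and inverse span
#' z-scores), digit span (likewise), Grober--Buschke total recall, DMS
#' immediate recall, Rey figure immediate and 3-minute copies, Stroop
#' interference time, TMT B minus A time, BREF, phonematic fluency, semantic
#' fluency and DO80 naming. Timed scores (Stroop, TMT B-A) are
#' lower-is-better and are negated before standardisation so that a higher
#' oriented score always means better performance.
#'
#' @return list of subtest specifications, each with elements \code{name},
#'   \code{components} (raw column names), \code{orientation}
#'   (\code{"higher_is_better"} or \code{"lower_is_better"}) and
#'   \code{reduction} (\code{"single"}, \code{"mean_of_z"} or
#'   \code{"difference"}; a difference takes component1 - component2).
#' @export
default_battery <- function() {
  sub <- function(name, components, orientation = "higher_is_better",
                  reduction = "single")
    list(name = name, components = components,
         orientation = orientation, reduction = reduction)
  list(
    sub("mmse", "mmse"),
    sub("mattis", "mattis"),
    sub("corsi", c("corsi_direct", "corsi_inverse"), reduction = "mean_of_z"),
    sub("digit_span", c("digit_direct", "digit_inverse"),
        reduction = "mean_of_z"),
    sub("grober_buschke", "grober_buschke_total_recall"),
    sub("dms", "dms_immediate"),
    sub("rey_immediate", "rey_immediate"),
    sub("rey_3min", "rey_3min"),
    sub("stroop", "stroop_interference_time",
        orientation = "lower_is_better"),
    sub("tmt_b_minus_a", c("tmt_b_time", "tmt_a_time"),
        orientation = "lower_is_better", reduction = "difference"),
    sub("bref", "bref"),
    sub("phonematic_fluency", "phonematic_fluency"),
    sub("semantic_fluency", "semantic_fluency"),
    sub("do80", "do80"))
}

#' Reduce raw battery columns to oriented subtest scores
#'
#' Applies each subtest specification: \code{single} passes the raw column
#' through; \code{difference} computes component1 - component2 (e.g. TMT B-A
#' time); \code{mean_of_z} z-scores each component column across the cohort
#' and averages the component z-scores. Lower-is-better values are negated
#' before any standardisation so orientation is consistent across subtests.
#'
#' @param battery data.frame of raw scores, one row per subject, with a
#'   \code{subject_id} column plus the raw columns named by \code{spec}.
#' @param spec battery definition as produced by \code{\link{default_battery}}.
#' @return numeric matrix (subjects x K) of oriented subtest scores, with
#'   rownames from \code{subject_id} and colnames from the subtest names.
#' @export
reduce_battery <- function(battery, spec = default_battery()) {
  if (nrow(battery) < 2) stop("need at least 2 subjects", call. = FALSE)
  needed <- unique(unlist(lapply(spec, `[[`, "components")))
  missing_cols <- setdiff(needed, names(battery))
  if (length(missing_cols))
    stop("battery columns not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  cols <- lapply(spec, function(s) {
    stopifnot(s$reduction %in% c("single", "mean_of_z", "difference"),
              s$orientation %in% c("higher_is_better", "lower_is_better"))
    sgn <- if (s$orientation == "lower_is_better") -1 else 1
    x <- switch(s$reduction,
      single = battery[[s$components[1]]],
      difference = {
        if (length(s$components) != 2)
          stop("difference reduction needs exactly 2 components: ", s$name,
               call. = FALSE)
        battery[[s$components[1]]] - battery[[s$components[2]]]
      },
      mean_of_z = {
        z <- vapply(s$components,
                    function(cc) zscore_col(sgn * battery[[cc]], cc),
                    numeric(nrow(battery)))
        return(rowMeans(z))  # orientation already applied per component
      })
    sgn * x
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(as.character(battery$subject_id),
                      vapply(spec, `[[`, "", "name"))
  m
}

zscore_col <- function(x, name) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("degenerate (zero-variance) subtest column: ", name, call. = FALSE)
  (x - mean(x, na.rm = TRUE)) / s
}

#' Cohort-wise z-transformation of subtest scores
#'
#' Standardises each subtest column on the basis of the whole subject
#' sample: Z = (x - mean) / sd with the sample (n-1) standard deviation, so
#' every column has mean 0 and SD 1.
#'
#' @param scores numeric matrix (subjects x K) of oriented subtest scores.
#' @return matrix of z-scores with the same dimnames.
#' @export
zscore_cohort <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) stop("need at least 2 subjects", call. = FALSE)
  nm <- colnames(scores)
  if (is.null(nm)) nm <- paste0("subtest_", seq_len(ncol(scores)))
  z <- vapply(seq_len(ncol(scores)),
              function(j) zscore_col(scores[, j], nm[j]),
              numeric(nrow(scores)))
  dimnames(z) <- dimnames(scores)
  z
}

#' Subject mean z-score across the battery
#'
#' @param z numeric vector of one subject's K z-scores, or a subjects x K
#'   matrix (one mean per row).
#' @return the mean z-score A = (1/K) sum_k Z_k.
#' @export
subject_mean <- function(z) {
  if (is.matrix(z)) {
    if (ncol(z) < 1) stop("empty z-score row", call. = FALSE)
    return(rowMeans(z))
  }
  if (length(z) < 1) stop("empty z-score row", call. = FALSE)
  mean(z)
}

#' Intra-person across-test variability V
#'
#' V is the sample standard deviation of one subject's z-scores across the
#' K subtests: sqrt(sum_k (Z_k - A)^2 / (K - 1)), A the subject's mean
#' z-score. High V means inconsistent performance across cognitive domains.
#'
#' @param z numeric vector of K >= 2 z-scores, or a subjects x K matrix
#'   (one V per row).
#' @return non-negative variability value(s); 0 iff all z-scores are equal.
#' @examples
#' across_test_variability(c(1, -1))     # sqrt(2)
#' across_test_variability(c(1, 0, -1))  # 1
#' @export
across_test_variability <- function(z) {
  if (is.matrix(z)) {
    if (ncol(z) < 2) stop("need K >= 2 subtests", call. = FALSE)
    return(apply(z, 1L, stats::sd))
  }
  if (length(z) < 2) stop("need K >= 2 subtests", call. = FALSE)
  stats::sd(z)
}

#' Per-subject variability results for a cohort
#'
#' Composes the battery reduction, cohort z-transformation and the per-row
#' mean/SD statistics into one table.
#'
#' Missing raw scores are an error by default (the V denominator K - 1 is
#' explicit, so silent changes of K must be visible). With
#' \code{missing = "available"} a subject's A and V are computed over their
#' observed subtests provided at least \code{min_k} are available;
#' \code{k_used} records the count. Cohort means/SDs for z-scoring always
#' use complete observations per column.
#'
#' @inheritParams reduce_battery
#' @param missing \code{"error"} (default) or \code{"available"}.
#' @param min_k minimum number of observed subtests under
#'   \code{missing = "available"}.
#' @return data.frame: \code{subject_id}, \code{a_i} (mean z-score),
#'   \code{v_i} (across-test variability), \code{k_used}.
#' @export
cohort_variability <- function(battery, spec = default_battery(),
                               missing = c("error", "available"),
                               min_k = 8) {
  missing <- match.arg(missing)
  oriented <- reduce_battery(battery, spec)
  if (anyNA(oriented)) {
    bad <- rownames(oriented)[apply(oriented, 1, anyNA)]
    if (missing == "error")
      stop("missing subtest scores for subjects: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  z <- zscore_cohort(oriented)
  k_used <- rowSums(!is.na(z))
  if (any(k_used < min_k))
    stop("fewer than min_k = ", min_k, " observed subtests for subjects: ",
         paste(rownames(z)[k_used < min_k], collapse = ", "), call. = FALSE)
  data.frame(
    subject_id = rownames(z),
    a_i = rowMeans(z, na.rm = TRUE),
    v_i = apply(z, 1L, stats::sd, na.rm = TRUE),
    k_used = as.integer(k_used),
    row.names = NULL, stringsAsFactors = FALSE)
}
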