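#' Decision thresholds for the two indices
#'
#' Published cutoffs: a nodule is suspicious for malignancy when
#' `WOind >= -19` (limited wash-out, i.e. tracer retention) or when
#' `R.I. >= -11.94`. Both boundaries are inclusive: a value exactly at the
#' cutoff is called suspicious.
#'
#' @param woind_cutoff_percent WOind cutoff, default -19.
#' @param ri_cutoff R.I. cutoff, default -11.94.
#' @return An object of class `decision_thresholds`.
#' @export
decision_thresholds <- function(woind_cutoff_percent = -19,
                                ri_cutoff = -11.94) {
  structure(list(woind_cutoff_percent = woind_cutoff_percent,
                 ri_cutoff = ri_cutoff,
                 boundary_rule = "inclusive"),
            class = "decision_thresholds")
}

#' Classify an index value as suspicious or benign
#'
#' @param index An [index_result], or a bare numeric value (then `method`
#'   must be given).
#' @param thresholds A [decision_thresholds].
#' @param method `"WOind"` or `"RI"`; taken from `index` when it is an
#'   `index_result`.
#' @param patient_id Optional identifier carried into the decision.
#' @return A `decision` object: `patient_id`, `method`, `call`
#'   (`"suspicious"` / `"benign"`), `index_value`.
#' @export
classify <- function(index, thresholds = decision_thresholds(),
                     method = NULL, patient_id = NA_integer_) {
  if (inherits(index, "index_result")) {
    method <- index$method
    value <- index$value
  } else {
    value <- as.numeric(index)
    method <- match.arg(method, c("WOind", "RI"))
  }
  if (!is.finite(value)) stop(format_error("index value must be finite"))
  cutoff <- switch(method,
                   WOind = thresholds$woind_cutoff_percent,
                   RI = thresholds$ri_cutoff)
  structure(
    list(patient_id = patient_id, method = method,
         call = if (value >= cutoff) "suspicious" else "benign",
         index_value = value),
    class = "decision"
  )
}

#' Classify a whole cohort by one method
#'
#' @param records Cohort data frame from [load_cohort_table()].
#' @param method `"WOind"` or `"RI"`.
#' @param thresholds A [decision_thresholds].
#' @return List of `decision` objects, one per record, in table order.
#' @export
classify_cohort <- function(records, method = c("WOind", "RI"),
                            thresholds = decision_thresholds()) {
  method <- match.arg(method)
  col <- if (method == "WOind") "woind_percent" else "ri"
  lapply(seq_len(nrow(records)), function(i) {
    classify(records[[col]][i], thresholds, method = method,
             patient_id = records$patient_id[i])
  })
}

#' Diagnostic performance against histology
#'
#' Cross-tabulates suspicious/benign calls against the histological truth
#' (malignant if and only if histology is differentiated thyroid cancer)
#' and reports sensitivity, specificity, accuracy, PPV and NPV as
#' percentages with exact (Clopper-Pearson) 95 percent confidence
#' intervals. A metric whose denominator is zero is reported as `NA` with a
#' reason, never silently as 0.
#'
#' @param decisions List of `decision` objects (see [classify()]).
#' @param records Cohort data frame with `patient_id` and `histology`.
#' @return A `performance_report`: `counts` (tp/fp/tn/fn), `metrics`
#'   (named percentages), `ci_95` (named 2-vectors), `undefined` (named
#'   reasons for any absent metric), `n`.
#' @export
evaluate <- function(decisions, records) {
  ids <- vapply(decisions, `[[`, numeric(1), "patient_id")
  if (length(ids) != nrow(records) ||
      !setequal(ids, records$patient_id) || anyDuplicated(ids)) {
    stop(format_error("decisions do not match the patient set one-to-one"))
  }
  truth <- records$histology[match(ids, records$patient_id)] == "DTC"
  call_pos <- vapply(decisions, `[[`, character(1), "call") == "suspicious"
  counts <- list(
    tp = sum(call_pos & truth), fp = sum(call_pos & !truth),
    tn = sum(!call_pos & !truth), fn = sum(!call_pos & truth)
  )
  performance_report(counts)
}

performance_report <- function(counts) {
  n <- counts$tp + counts$fp + counts$tn + counts$fn
  defs <- list(
    sensitivity = c(counts$tp, counts$tp + counts$fn, "no malignant cases"),
    specificity = c(counts$tn, counts$tn + counts$fp, "no benign cases"),
    accuracy    = c(counts$tp + counts$tn, n, "no cases"),
    ppv         = c(counts$tp, counts$tp + counts$fp, "no suspicious calls"),
    npv         = c(counts$tn, counts$tn + counts$fn, "no benign calls")
  )
  metrics <- ci <- list(); undefined <- list()
  for (nm in names(defs)) {
    x <- as.integer(defs[[nm]][1]); d <- as.integer(defs[[nm]][2])
    if (d == 0) {
      metrics[[nm]] <- NA_real_
      undefined[[nm]] <- defs[[nm]][3]
    } else {
      metrics[[nm]] <- 100 * x / d
      ci[[nm]] <- 100 * as.numeric(
        stats::binom.test(x, d)$conf.int)  # exact Clopper-Pearson
    }
  }
  structure(list(counts = counts, metrics = metrics, ci_95 = ci,
                 undefined = undefined, n = n),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  c <- x$counts
  cat(sprintf("<performance_report> n=%d  tp=%d fp=%d tn=%d fn=%d\n",
              x$n, c$tp, c$fp, c$tn, c$fn))
  for (nm in names(x$metrics)) {
    v <- x$metrics[[nm]]
    if (is.na(v)) {
      cat(sprintf("  %-11s undefined (%s)\n", nm, x$undefined[[nm]]))
    } else {
      ci <- x$ci_95[[nm]]
      cat(sprintf("  %-11s %6.1f%%  (95%% CI %.1f-%.1f)\n", nm, v,
                  ci[1], ci[2]))
    }
  }
  invisible(x)
}

#' Inter-method agreement
#'
#' Percentage of patients receiving the same suspicious/benign call from
#' two classification methods.
#'
#' @param decisions_a,decisions_b Decision lists over the same patient set.
#' @return Percentage in `[0, 100]`.
#' @export
agreement <- function(decisions_a, decisions_b) {
  ids_a <- vapply(decisions_a, `[[`, numeric(1), "patient_id")
  ids_b <- vapply(decisions_b, `[[`, numeric(1), "patient_id")
  if (!setequal(ids_a, ids_b) || anyDuplicated(ids_a) ||
      length(ids_a) != length(ids_b)) {
    stop(format_error("decision sets cover different patients"))
  }
  calls_a <- vapply(decisions_a, `[[`, character(1), "call")
  calls_b <- vapply(decisions_b, `[[`, character(1), "call")[match(ids_a, ids_b)]
  100 * mean(calls_a == calls_b)
}
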