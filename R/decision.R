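# Deterministic acuity decision logic over thresholded head outputs.

#' Decide the acuity state from thresholded head outputs
#'
#' Priority rules: `deceased` wins outright; otherwise `unstable` if any of
#' the five instability-indicating heads (`unstable`, `stable_to_unstable`,
#' `mv`, `vp`, `crrt`) is positive; otherwise `discharge` if the discharge
#' head is positive; otherwise `stable`. The `unstable_to_stable` head does
#' not enter the logic; it remains an evaluated output. The function is total
#' over all 2^7 binary input combinations.
#'
#' @param heads A data frame (or tibble) with binary columns `deceased`,
#'   `unstable`, `stable_to_unstable`, `mv`, `vp`, `crrt`, `discharge`.
#' @return Factor of states with levels
#'   `discharge < stable < unstable < deceased`, one per row.
#' @examples
#' decide_acuity(data.frame(deceased = 1, unstable = 1, stable_to_unstable = 1,
#'                          mv = 1, vp = 1, crrt = 1, discharge = 1))
#' @export
decide_acuity <- function(heads) {
  need <- c("deceased", "unstable", "stable_to_unstable", "mv", "vp", "crrt",
            "discharge")
  miss <- setdiff(need, names(heads))
  if (length(miss)) abort(paste("missing head columns:",
                                paste(miss, collapse = ", ")))
  h <- lapply(heads[need], function(v) {
    if (!all(v %in% c(0, 1))) abort("head outputs must be binary 0/1")
    as.integer(v)
  })
  any_unstable <- pmax(h$unstable, h$stable_to_unstable, h$mv, h$vp, h$crrt)
  state <- ifelse(h$deceased == 1L, "deceased",
                  ifelse(any_unstable == 1L, "unstable",
                         ifelse(h$discharge == 1L, "discharge", "stable")))
  factor(state, levels = ACUITY_LEVELS)
}

#' Threshold head probabilities and decide acuity per window
#'
#' Applies per-head thresholds to a prediction tibble and appends the decided
#' `state` column.
#'
#' @param probs Prediction tibble from [predict.acuity_model()].
#' @param thresholds Named thresholds from [select_thresholds()]; heads with
#'   `NA` threshold are treated as never positive.
#' @return `probs` with added binary `b_<head>` columns and a `state` column.
#' @export
apply_decision_logic <- function(probs, thresholds) {
  b <- lapply(c("deceased", "unstable", "stable_to_unstable", "mv", "vp",
                "crrt", "discharge"), function(h) {
    thr <- thresholds[[h]]
    p <- probs[[paste0("p_", h)]]
    if (is.null(thr) || is.na(thr)) rep(0L, length(p))
    else as.integer(p >= thr)
  })
  names(b) <- c("deceased", "unstable", "stable_to_unstable", "mv", "vp",
                "crrt", "discharge")
  bt <- tibble::as_tibble(b)
  out <- dplyr::bind_cols(probs,
                          stats::setNames(bt, paste0("b_", names(bt))))
  out$state <- decide_acuity(bt)
  out
}
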