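# CRT response: endpoint derivation from paired echocardiography, echo-ECG
# linkage, and response modeling against tree variables.

#' Derive CRT response endpoints from pre/post echo pairs
#'
#' Three responder definitions, evaluated between pre-CRT and 6-month
#' post-CRT echocardiography: LVEF improvement of at least 10 percentage
#' points (absolute difference), and relative reductions of at least 15%
#' in LV end-systolic diameter (LVESD) and LV end-systolic volume (LVESV).
#' A missing member of a pair leaves that endpoint undefined (`NA`), never
#' `FALSE`; a zero pre value makes a relative endpoint undefined and raises
#' a warning. The endpoints are pure functions of the echo pair.
#'
#' @param records data frame with columns `pre_lvef`, `post_lvef`,
#'   `pre_lvesd`, `post_lvesd`, `pre_lvesv`, `post_lvesv` (any subset).
#' @param lvef_abs_pts absolute LVEF threshold in percentage points.
#' @param rel_frac relative reduction threshold for LVESD/LVESV.
#' @return the input with logical columns `resp_lvef`, `resp_lvesd`,
#'   `resp_lvesv` appended (NA where undefined).
#' @export
compute_crt_endpoints <- function(records, lvef_abs_pts = 10, rel_frac = 0.15) {
  d <- records
  getcol <- function(nm) if (nm %in% names(d)) d[[nm]] else rep(NA_real_, nrow(d))
  pre_ef <- getcol("pre_lvef");  post_ef <- getcol("post_lvef")
  pre_sd <- getcol("pre_lvesd"); post_sd <- getcol("post_lvesd")
  pre_sv <- getcol("pre_lvesv"); post_sv <- getcol("post_lvesv")
  rel_resp <- function(pre, post) {
    out <- (pre - post) / pre >= rel_frac
    zero <- !is.na(pre) & pre == 0 & !is.na(post)
    if (any(zero)) {
      warnf("%d record(s) with zero pre value: relative endpoint undefined", sum(zero))
      out[zero] <- NA
    }
    out
  }
  d$resp_lvef <- (post_ef - pre_ef) >= lvef_abs_pts
  d$resp_lvesd <- rel_resp(pre_sd, post_sd)
  d$resp_lvesv <- rel_resp(pre_sv, post_sv)
  d
}

#' Link echocardiograms to ECGs within a day window
#'
#' Each ECG is linked to the nearest echo within `window_days` (inclusive);
#' one echo may serve several ECGs. Ties in distance go to the earlier
#' echo. The result is independent of row order in either table.
#'
#' @param ecgs data frame with `id` and `ecg_day` (numeric day index or Date).
#' @param echos data frame with `echo_id` and `echo_day`, plus any
#'   measurement columns to carry along.
#' @param window_days maximum |echo - ECG| separation in days.
#' @return tibble of linked pairs: ECG columns, matched `echo_id`,
#'   `link_days` (signed echo - ECG offset) and the echo's columns.
#' @export
link_echo_to_ecg <- function(ecgs, echos, window_days = 60) {
  stopifnot(all(c("id", "ecg_day") %in% names(ecgs)),
            all(c("echo_id", "echo_day") %in% names(echos)))
  eo <- echos[order(as.numeric(echos$echo_day), echos$echo_id), , drop = FALSE]
  rows <- lapply(seq_len(nrow(ecgs)), function(i) {
    delta <- as.numeric(eo$echo_day) - as.numeric(ecgs$ecg_day[i])
    ok <- which(abs(delta) <= window_days)
    if (!length(ok)) return(NULL)
    best <- ok[order(abs(delta[ok]), as.numeric(eo$echo_day)[ok])][1]
    cbind(ecgs[i, , drop = FALSE],
          eo[best, setdiff(names(eo), names(ecgs)), drop = FALSE],
          link_days = delta[best])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(tibble::tibble())
  tibble::as_tibble(out)
}

#' Model CRT response against tree variables
#'
#' Logistic regression of a responder endpoint on tree-derived predictors,
#' adjusted for age, sex and QRS duration. By default the fit is restricted
#' to LBBB-labeled records, the population in which CRT is indicated and
#' analyzed.
#'
#' @param records data frame containing the endpoint (see
#'   [compute_crt_endpoints()]), the predictors, the adjustment covariates
#'   and a `morphology` column.
#' @param endpoint endpoint column name (`"resp_lvef"`, `"resp_lvesd"` or
#'   `"resp_lvesv"`).
#' @param predictors tree variables, from
#'   `{dim1, dim2, pseudotime_branch, phenogroup}`.
#' @param covariates adjustment set (age, sex, QRS duration).
#' @param lbbb_only restrict to LBBB-labeled records.
#' @param min_records minimum records with a defined endpoint.
#' @return tibble as from [fit_adjusted_model()] (odds ratios).
#' @export
model_crt_response <- function(records, endpoint = "resp_lvesd",
                               predictors = c("dim1", "dim2"),
                               covariates = c("age", "sex", "qrs_ms"),
                               lbbb_only = TRUE, min_records = 20) {
  d <- as.data.frame(records)
  if (lbbb_only) {
    if (!"morphology" %in% names(d)) stopf("records lack a morphology column")
    d <- d[d$morphology == "LBBB", , drop = FALSE]
  }
  if (!endpoint %in% names(d)) stopf("endpoint column '%s' not found", endpoint)
  d <- d[!is.na(d[[endpoint]]), , drop = FALSE]
  if (nrow(d) < min_records)
    stopf("only %d records with a defined %s endpoint (need >= %d)",
          nrow(d), endpoint, min_records)
  d[[endpoint]] <- as.integer(d[[endpoint]])
  fit_adjusted_model(d, outcome = endpoint, predictors = predictors,
                     covariates = covariates, kind = "logistic")
}
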