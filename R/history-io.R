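#' Assemble a trial history from tabulated interim data
#'
#' Builds the container consumed by the post-trial analyses from a
#' long-format table of cumulative counts -- the form in which the record
#' of a real trial is naturally kept. Validation mirrors [load_history()]:
#' successes cannot exceed patients, cumulative counts cannot decrease, and
#' each arm's interims must be contiguous from 1.
#'
#' @param design The [design_spec()] under which the trial was run.
#' @param table Data frame with columns `arm`, `stratum`, `interim`,
#'   `cum_n`, `cum_S`; one row per arm x stratum x interim the arm was
#'   present.
#' @param eliminated_by Optional integer vector: for each arm, the arm that
#'   eliminated it (`NA` for survivors). Informational; the
#'   reverse-simulation consistency rules recompute conclusions from the
#'   data.
#' @param outcome Optional list describing the terminal outcome (`kind`,
#'   `winners`, `total_n`, `stop_reason`).
#' @return A `trial_history`.
#' @export
trial_history <- function(design, table, eliminated_by = NULL,
                          outcome = NULL) {
  stopifnot(inherits(design, "design_spec"))
  need <- c("arm", "stratum", "interim", "cum_n", "cum_S")
  if (!all(need %in% names(table)))
    stop("history table must have columns ", paste(need, collapse = ", "))
  na <- design$n_arms; nc <- design$n_strata
  if (any(table$arm < 1 | table$arm > na))
    stop("arm index outside 1..", na)
  if (any(table$stratum < 1 | table$stratum > nc))
    stop("stratum index outside 1..", nc)
  last <- as.integer(tapply(table$interim, table$arm, max)[as.character(seq_len(na))])
  if (anyNA(last)) stop("every arm needs at least one interim row")
  K <- max(last)
  n_arr <- array(NA_real_, c(na, nc, K))
  s_arr <- array(NA_real_, c(na, nc, K))
  table <- table[order(table$arm, table$stratum, table$interim), ]
  for (r in seq_len(nrow(table))) {
    a <- table$arm[r]; c <- table$stratum[r]; k <- table$interim[r]
    if (k < 1 || k > last[a])
      .schema_fail(r, "interim index out of range")
    if (table$cum_S[r] > table$cum_n[r]) .schema_fail(r, "cum_S exceeds cum_n")
    if (table$cum_n[r] < 0 || table$cum_S[r] < 0)
      .schema_fail(r, "negative count")
    n_arr[a, c, k] <- table$cum_n[r]
    s_arr[a, c, k] <- table$cum_S[r]
    if (k > 1L) {
      if (is.na(n_arr[a, c, k - 1L])) .schema_fail(r, "missing earlier interim")
      if (table$cum_n[r] < n_arr[a, c, k - 1L])
        .schema_fail(r, "cum_n decreases between interims")
      if (table$cum_S[r] < s_arr[a, c, k - 1L])
        .schema_fail(r, "cum_S decreases between interims")
    }
  }
  for (a in seq_len(na))
    if (anyNA(n_arr[a, , seq_len(last[a])]))
      stop(sprintf("arm %d: missing interim rows", a))
  if (is.null(eliminated_by)) eliminated_by <- rep(NA_integer_, na)
  if (is.null(outcome))
    outcome <- list(kind = "unspecified", winners = integer(0),
                    total_n = sum(vapply(seq_len(na),
                                         function(a) sum(n_arr[a, , last[a]]),
                                         0)),
                    stop_reason = "unspecified")
  .new_trial_history(design, n_arr, s_arr, last,
                     as.integer(eliminated_by), K, outcome,
                     decisions = NULL)
}

#' Long-format table of a trial history
#'
#' @param history A `trial_history`.
#' @return Data frame with columns `arm`, `stratum`, `interim`, `cum_n`,
#'   `cum_S`, one row per arm x stratum x interim the arm was present.
#' @export
history_table <- function(history) {
  stopifnot(inherits(history, "trial_history"))
  rows <- list()
  for (i in seq_len(history$n_arms))
    for (c in seq_len(history$n_strata)) {
      ks <- seq_len(history$last_interim[i])
      rows[[length(rows) + 1L]] <-
        data.frame(arm = i, stratum = c, interim = ks,
                   cum_n = as.integer(history$n[i, c, ks]),
                   cum_S = as.integer(history$S[i, c, ks]))
    }
  do.call(rbind, rows)
}

#' @rdname history_table
#' @param x A `trial_history`.
#' @param ... Unused.
#' @export
as.data.frame.trial_history <- function(x, ...) history_table(x)

#' Write a trial history to CSV plus a JSON sidecar
#'
#' The CSV is the long-format table of [history_table()]; the sidecar
#' records the design preset name, per-arm elimination record, final interim
#' index and terminal outcome, so that [load_history()] can round-trip the
#' object.
#'
#' @param history A `trial_history`.
#' @param path CSV file path.
#' @param sidecar_path JSON path; defaults to `path` with a `.json`
#'   extension appended.
#' @return `path`, invisibly.
#' @export
save_history <- function(history, path, sidecar_path = paste0(path, ".json")) {
  utils::write.csv(history_table(history), path, row.names = FALSE,
                   quote = FALSE)
  meta <- list(design = if (is.null(history$design$name)) NA
               else history$design$name,
               n_arms = history$n_arms, n_strata = history$n_strata,
               K = history$K,
               last_interim = history$last_interim,
               eliminated_by = history$eliminated_by,
               outcome = history$outcome[c("kind", "winners", "total_n",
                                           "stop_reason")])
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

.schema_fail <- function(row, msg)
  stop(sprintf("invalid trial history at row %d: %s", row, msg))

#' Read a trial history from CSV (+ JSON sidecar)
#'
#' Validates the schema on load: cumulative counts must be nondecreasing in
#' the interim index, successes cannot exceed patients, and each arm's
#' interims must run 1, 2, ... without gaps. Violations raise an error
#' naming the offending row.
#'
#' @param path CSV file as written by [save_history()].
#' @param sidecar_path JSON sidecar path.
#' @param design A [design_spec()]; if `NULL`, the preset named in the
#'   sidecar is loaded.
#' @return A `trial_history`.
#' @export
load_history <- function(path, sidecar_path = paste0(path, ".json"),
                         design = NULL) {
  if (!file.exists(path)) stop("history file not found: ", path)
  if (!file.exists(sidecar_path))
    stop("sidecar file not found: ", sidecar_path)
  tab <- utils::read.csv(path)
  need <- c("arm", "stratum", "interim", "cum_n", "cum_S")
  if (!all(need %in% names(tab)))
    stop("history CSV must have columns ", paste(need, collapse = ", "))
  meta <- jsonlite::fromJSON(sidecar_path, simplifyVector = TRUE)
  if (is.null(design)) {
    if (is.null(meta$design) || is.na(meta$design))
      stop("no design preset in sidecar; pass 'design' explicitly")
    design <- design_preset(meta$design, n_strata = meta$n_strata)
  }
  outcome <- meta$outcome
  outcome$winners <- as.integer(outcome$winners)
  h <- trial_history(design, tab,
                     eliminated_by = suppressWarnings(
                       as.integer(meta$eliminated_by)),
                     outcome = outcome)
  if (h$K != meta$K)
    stop("sidecar K disagrees with the table's final interim")
  h
}
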