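# Behavioural (WECS) aggregation and dyad classification.

#' Aggregate WECS codes to per-(action, domain) means
#'
#' Raw scores are averaged across the four iterations of each action.
#' Iterations whose behavioural state is `inconsolable` are eliminated
#' before averaging (inconsolability confounds facial coding); drowsy
#' iterations remain included, with their sensitivity score of 0 entering
#' the mean as coded (set `drop_drowsy = TRUE` to exclude drowsy iterations
#' instead). An (action, domain) cell with no remaining iterations is
#' missing.
#'
#' @param wecs validated WECS table (see [read_wecs()]).
#' @param drop_drowsy exclude drowsy iterations from all domains.
#' @return `data.frame`: `infant_id`, `action`, `domain`, `mean_score`,
#'   `n_iterations`.
#' @export
aggregate_wecs <- function(wecs, drop_drowsy = FALSE) {
  wecs <- validate_wecs(wecs)
  keep <- wecs$state != "inconsolable"
  if (drop_drowsy) keep <- keep & wecs$state != "drowsy"
  dt <- data.table::as.data.table(wecs[keep, ])
  full <- data.table::CJ(infant_id = unique(wecs$infant_id),
                         action = 1:4,
                         domain = c("facial", "sensitivity", "vocal"))
  agg <- dt[, list(mean_score = mean(score), n_iterations = .N),
            by = c("infant_id", "action", "domain")]
  out <- agg[full, on = c("infant_id", "action", "domain")]
  out$n_iterations[is.na(out$n_iterations)] <- 0L
  data.table::setorderv(out, c("infant_id", "action", "domain"))
  as.data.frame(out)
}

#' Classify infant irritability
#'
#' An infant is irritable when it was inconsolable at any point during the
#' interaction or needed consoling more than once. An infant irritable only
#' when initially approached (a single consoling event, never inconsolable)
#' is classified not irritable.
#'
#' @param meta one-row dyad metadata (or data.frame; vectorised).
#' @return logical vector.
#' @export
classify_irritability <- function(meta) {
  as.logical(meta$ever_inconsolable) | meta$consoling_events > 1
}

#' Classify maternal bondedness from the MIBS
#'
#' MIBS 0 or 1: `"more"` bonded; MIBS >= 2: `"less"` bonded (the
#' conventional at-risk threshold).
#'
#' @param meta dyad metadata with `mibs` in 0-24.
#' @return factor with levels `more`, `less`.
#' @export
classify_bondedness <- function(meta) {
  if (any(meta$mibs < 0 | meta$mibs > 24))
    stop("MIBS out of range 0-24")
  factor(ifelse(meta$mibs <= 1, "more", "less"), levels = c("more", "less"))
}

#' Screen for maternal depression risk from the EPDS
#'
#' At-risk threshold EPDS >= 10 (conservative). Cohort-level helper
#' [depression_covariate_needed()] mirrors the practice of dropping the
#' depression covariate entirely when no mother meets the threshold.
#'
#' @param meta dyad metadata with `epds` in 0-30.
#' @return logical vector.
#' @export
screen_depression <- function(meta) {
  if (any(meta$epds < 0 | meta$epds > 30))
    stop("EPDS out of range 0-30")
  meta$epds >= 10
}

#' Should the depression covariate enter cohort models?
#' @param meta cohort metadata table.
#' @return `TRUE` when at least one mother screens at risk.
#' @export
depression_covariate_needed <- function(meta) any(screen_depression(meta))
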