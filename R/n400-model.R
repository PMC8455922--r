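# Combining the two components into a predicted N400 index, the end-to-end
# evaluation of a critical word against a scenario, and the thematic-role
# extension for schema-based knowledge.

#' Run configuration
#'
#' Collects the tunable knobs of the model in one validated object.
#'
#' @param log_base logarithm base for entropy and surprisal (default 10,
#'   the base on which the worked entropy values were computed).
#' @param threshold_r override for the scenarios' default-inference
#'   threshold; `NULL` keeps each scenario's own value.
#' @param alpha,beta weights of the predictability and plausibility terms
#'   of the index; must sum to 1.
#' @param extension_depth maximum attribute-chain depth n (default 3).
#' @param typicality_variant `"raw"` (the variant reproducing the worked
#'   values; default) or `"normalized"`.
#' @param tolerance absolute tolerance used when comparing against
#'   printed (rounded) values (default 0.005).
#' @param extension_cap maximum number of enumerated extensions.
#' @param seed optional integer seed for downstream simulation.
#' @return object of class `run_config`.
#' @export
run_config <- function(log_base = 10, threshold_r = NULL,
                       alpha = 0.5, beta = 0.5,
                       extension_depth = 3,
                       typicality_variant = c("raw", "normalized"),
                       tolerance = 0.005, extension_cap = 1e5,
                       seed = NULL) {
  typicality_variant <- match.arg(typicality_variant)
  if (!is.numeric(log_base) || log_base <= 1)
    stop("`log_base` must exceed 1", call. = FALSE)
  if (abs(alpha + beta - 1) > .prob_tol)
    stop("`alpha` and `beta` must sum to 1", call. = FALSE)
  if (!is.null(threshold_r) && (threshold_r < 0 || threshold_r >= 1))
    stop("`threshold_r` must lie in [0, 1)", call. = FALSE)
  structure(list(log_base = log_base, threshold_r = threshold_r,
                 alpha = alpha, beta = beta,
                 extension_depth = extension_depth,
                 typicality_variant = typicality_variant,
                 tolerance = tolerance, extension_cap = extension_cap,
                 seed = seed),
            class = "run_config")
}

#' Predicted N400 index from the two components
#'
#' The combining function is a package choice (any monotone combination is
#' admissible): a convex combination of the two complements,
#' `alpha * (1 - delta_h / delta_h_max) + beta * (1 - typ)`, strictly
#' decreasing in both entropy reduction and typicality. `delta_h_max` is
#' the entropy at t1 (full reduction). When `delta_h_max` is 0 there is
#' nothing to predict and the predictability term is dropped, so the index
#' is `beta * (1 - typ)`.
#'
#' @param delta_h entropy reduction, `0 <= delta_h <= delta_h_max`.
#' @param delta_h_max maximal attainable reduction (entropy at t1).
#' @param typ typicality in \[0, 1\].
#' @param alpha,beta component weights summing to 1.
#' @return index in \[0, 1\].
#' @export
n400_index <- function(delta_h, delta_h_max, typ, alpha = 0.5, beta = 0.5) {
  if (abs(alpha + beta - 1) > .prob_tol)
    stop("`alpha` and `beta` must sum to 1", call. = FALSE)
  if (delta_h < -.prob_tol || delta_h > delta_h_max + 1e-6)
    stop("`delta_h` must lie in [0, delta_h_max]", call. = FALSE)
  if (typ < -.prob_tol || typ > 1 + .prob_tol)
    stop("`typ` must lie in [0, 1]", call. = FALSE)
  pred_term <- if (delta_h_max > 0) alpha * (1 - delta_h / delta_h_max) else 0
  pred_term + beta * (1 - typ)
}

new_component_report <- function(cw, failed, failing_chains = character(0),
                                 h_t1 = NA_real_, h_t2 = NA_real_,
                                 delta_h = NA_real_,
                                 typicality_raw = NA_real_,
                                 typicality_normalized = NA_real_,
                                 n400_index = NA_real_,
                                 partition_sizes = c(conf = NA_integer_,
                                                     comp = NA_integer_,
                                                     disconf = NA_integer_),
                                 partition = NULL,
                                 typicality_report = NULL) {
  structure(list(cw = cw, failed = failed, failing_chains = failing_chains,
                 h_t1 = h_t1, h_t2 = h_t2, delta_h = delta_h,
                 typicality_raw = typicality_raw,
                 typicality_normalized = typicality_normalized,
                 n400_index = n400_index,
                 partition_sizes = partition_sizes,
                 partition = partition,
                 typicality_report = typicality_report),
            class = "component_report")
}

#' @export
print.component_report <- function(x, digits = 4, ...) {
  cat("<component_report>", x$cw, "\n")
  if (x$failed) {
    cat("  categorization FAILED on:",
        paste(x$failing_chains, collapse = ", "), "\n")
    cat("  n400_index:", x$n400_index, "(maximal; typicality not computed)\n")
    return(invisible(x))
  }
  cat("  entropy t1/t2:", round(x$h_t1, digits), "/", round(x$h_t2, digits),
      " reduction:", round(x$delta_h, digits), "\n")
  cat("  typicality raw:", round(x$typicality_raw, digits),
      " normalized:", round(x$typicality_normalized, digits), "\n")
  cat("  partition |conf|,|comp|,|disconf|:",
      paste(x$partition_sizes, collapse = ", "), "\n")
  cat("  n400_index:", round(x$n400_index, digits), "\n")
  invisible(x)
}

#' Evaluate a critical word against a scenario
#'
#' Runs the full pipeline: optional prenominal update, default inferences,
#' the three-way partition, the predictability component (entropy
#' reduction), the plausibility component (typicality), and the combined
#' index. On categorization failure (a pre-activated chain undefined for
#' the critical word's category) typicality is not computed and the index
#' takes its maximal value 1.
#'
#' @param spec a [scenario_spec()].
#' @param cw name of a declared critical word.
#' @param prenominal optional prenominal-update name.
#' @param config a [run_config()].
#' @return a `component_report` carrying every intermediate.
#' @examples
#' sc <- fixture_holiday_resort()
#' evaluate_cw(sc, "palms")
#' @export
evaluate_cw <- function(spec, cw, prenominal = NULL, config = run_config()) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(config, "run_config"))
  c_arg <- scenario_arg_concept(spec, prenominal = prenominal)
  if (!is.null(config$threshold_r)) c_arg$threshold_r <- config$threshold_r
  c_cw <- scenario_cw_concept(spec, cw)
  if (!is.null(config$threshold_r)) c_cw$threshold_r <- config$threshold_r
  part <- update_set(c_arg, c_cw)
  sizes <- c(conf = length(part$confirmed),
             comp = length(part$compatible),
             disconf = length(part$disconfirmed))
  if (part$failed) {
    return(new_component_report(cw, failed = TRUE,
                                failing_chains = part$failing_chains,
                                n400_index = 1,
                                partition_sizes = c(conf = NA_integer_,
                                                    comp = NA_integer_,
                                                    disconf = NA_integer_),
                                partition = part))
  }
  pc <- predictability_component(c_arg, part, n = config$extension_depth,
                                 base = config$log_base,
                                 cap = config$extension_cap)
  tp <- typicality(c_arg, c_cw, profile = diagnosticity(c_arg))
  typ_used <- switch(config$typicality_variant,
                     raw = tp$raw, normalized = tp$normalized)
  idx <- n400_index(pc$delta_h, pc$h_t1, typ_used,
                    alpha = config$alpha, beta = config$beta)
  new_component_report(cw, failed = FALSE,
                       h_t1 = pc$h_t1, h_t2 = pc$h_t2,
                       delta_h = pc$delta_h,
                       typicality_raw = tp$raw,
                       typicality_normalized = tp$normalized,
                       n400_index = idx,
                       partition_sizes = sizes,
                       partition = part,
                       typicality_report = tp)
}

#' Evaluate all critical words of a scenario
#'
#' @inheritParams evaluate_cw
#' @return named list of `component_report`s, one per critical word.
#' @export
evaluate_scenario <- function(spec, prenominal = NULL,
                              config = run_config()) {
  stats::setNames(
    lapply(names(spec$critical_words), evaluate_cw, spec = spec,
           prenominal = prenominal, config = config),
    names(spec$critical_words))
}

#' Tabulate component reports
#'
#' Fixed column order: cw, failed, h_t1, h_t2, delta_h, typicality_raw,
#' typicality_normalized, n400_index, n_conf, n_comp, n_disconf.
#'
#' @param reports a `component_report` or list of them.
#' @return data.frame, one row per critical word.
#' @export
report_table <- function(reports) {
  if (inherits(reports, "component_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r)
    data.frame(cw = r$cw, failed = r$failed,
               h_t1 = r$h_t1, h_t2 = r$h_t2, delta_h = r$delta_h,
               typicality_raw = r$typicality_raw,
               typicality_normalized = r$typicality_normalized,
               n400_index = r$n400_index,
               n_conf = as.integer(r$partition_sizes[["conf"]]),
               n_comp = as.integer(r$partition_sizes[["comp"]]),
               n_disconf = as.integer(r$partition_sizes[["disconf"]]),
               stringsAsFactors = FALSE, row.names = NULL)))
}

#' Serialize component reports
#'
#' @param reports a `component_report` or list of them.
#' @param format `"json"` or `"tsv"`.
#' @return a character scalar (JSON at full precision, or TSV with the
#'   [report_table()] column order).
#' @export
format_reports <- function(reports, format = c("json", "tsv")) {
  format <- match.arg(format)
  tab <- report_table(reports)
  if (format == "json") {
    as.character(jsonlite::toJSON(tab, dataframe = "rows", na = "null",
                                  auto_unbox = TRUE, digits = NA))
  } else {
    paste(c(paste(names(tab), collapse = "\t"),
            apply(tab, 1L, function(row) paste(trimws(row),
                                               collapse = "\t"))),
          collapse = "\n")
  }
}

#' Thematic-role typicality for schema-based knowledge
#'
#' When several argument concepts are active (one per thematic role), each
#' pre-activated feature is prefixed with its role, and the role's
#' diagnosticity is the expectation that the critical word provides
#' information about that role (highest for undischarged arguments; the
#' weights are scenario data). The overall value is the role-weighted sum
#' of inner typicalities; a role whose profiled chains (selection
#' restrictions such as animacy) are undefined for the critical word's
#' category contributes 0.
#'
#' @param roles list of role specifications, each a `list(role, weight,
#'   c_arg, profile)` with `c_arg` a [category_concept()] and `profile`
#'   an optional [diagnosticity()] profile (defaults to
#'   `diagnosticity(c_arg)`). Weights must sum to 1.
#' @param c_cw the critical word's [category_concept()].
#' @return real in \[0, 1\].
#' @export
role_typicality <- function(roles, c_cw) {
  w <- vapply(roles, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > .prob_tol)
    stop("role weights must sum to 1", call. = FALSE)
  total <- 0
  for (role in roles) {
    profile <- role$profile
    if (is.null(profile)) profile <- diagnosticity(role$c_arg)
    if (length(setdiff(names(profile$weights), frame_chains(c_cw$frame))))
      next  # selection restrictions undefined: zero contribution
    total <- total + role$weight * typicality(role$c_arg, c_cw,
                                              profile = profile)$raw
  }
  total
}
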