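# Scenario JSON format: writing, loading with renormalization, and the
# itemized validation pathway. Numbers are serialized at full precision;
# rounding happens only at the presentation layer.

dist_block_to_plain <- function(dists) {
  lapply(dists, function(p) as.list(p))
}

plain_to_dist_block <- function(x, renorm_tol = 1e-6) {
  out <- lapply(x, function(p) {
    v <- stats::setNames(as.numeric(unlist(p)), names(p))
    s <- sum(v)
    if (is.finite(s) && s > 0 && abs(s - 1) <= renorm_tol && s != 1)
      v <- v / s
    v
  })
  out
}

scenario_to_plain <- function(spec) {
  list(
    format_version = spec$format_version,
    name = spec$name,
    constraint_level = spec$constraint_level,
    sorts = lapply(seq_len(nrow(spec$sorts)), function(i)
      list(name = spec$sorts$name[i],
           parent = if (is.na(spec$sorts$parent[i])) NULL
                    else spec$sorts$parent[i])),
    attributes = spec$attributes,
    categories = lapply(spec$categories, function(cat_)
      list(sort = cat_$sort,
           distributions = dist_block_to_plain(cat_$distributions))),
    arg_concept = {
      arg <- spec$arg_concept
      out <- list(category = arg$category,
                  context_independent = as.list(arg$context_independent),
                  context_dependent = as.list(arg$context_dependent),
                  threshold_r = arg$threshold_r)
      if (!is.null(arg$diagnosticity))
        out$diagnosticity <- as.list(arg$diagnosticity)
      if (!is.null(arg$contrasts))
        out$contrasts <- lapply(arg$contrasts, function(ct)
          list(name = ct$name,
               distributions = dist_block_to_plain(ct$distributions)))
      if (!is.null(arg$provenance)) out$provenance <- arg$provenance
      out
    },
    prenominal_updates = lapply(spec$prenominal_updates, function(u)
      list(chain = u$chain, value = u$value,
           revisions = dist_block_to_plain(u$revisions))),
    critical_words = spec$critical_words,
    roles = spec$roles)
}

plain_to_scenario <- function(x, source = "<in-memory>") {
  known <- c("format_version", "name", "constraint_level", "sorts",
             "attributes", "categories", "arg_concept",
             "prenominal_updates", "critical_words", "roles")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    warning("unknown field(s) in ", source, " ignored: ",
            paste(unknown, collapse = ", "))
  arg <- x$arg_concept
  arg_out <- list(
    category = arg$category,
    context_independent = as.character(unlist(arg$context_independent)),
    context_dependent = as.character(unlist(arg$context_dependent)),
    threshold_r = as.numeric(arg$threshold_r))
  if (!is.null(arg$diagnosticity))
    arg_out$diagnosticity <- stats::setNames(
      as.numeric(unlist(arg$diagnosticity)), names(arg$diagnosticity))
  if (!is.null(arg$contrasts))
    arg_out$contrasts <- lapply(arg$contrasts, function(ct)
      list(name = ct$name,
           distributions = plain_to_dist_block(ct$distributions)))
  if (!is.null(arg$provenance))
    arg_out$provenance <- lapply(arg$provenance, function(e)
      if (is.list(e)) unlist(e) else e)
  scenario_spec(
    name = x$name,
    constraint_level = x$constraint_level,
    sorts = x$sorts,
    attributes = lapply(x$attributes, function(v) as.character(unlist(v))),
    categories = lapply(x$categories, function(cat_)
      list(sort = cat_$sort,
           distributions = plain_to_dist_block(cat_$distributions))),
    arg_concept = arg_out,
    prenominal_updates = lapply(x$prenominal_updates, function(u)
      list(chain = u$chain, value = u$value,
           revisions = plain_to_dist_block(u$revisions))),
    critical_words = lapply(x$critical_words, function(cw)
      list(category = cw$category)),
    roles = if (!is.null(x$roles) && length(x$roles))
      lapply(x$roles, function(r)
        list(weight = as.numeric(r$weight), category = r$category,
             profile = if (!is.null(r$profile))
               stats::setNames(as.numeric(unlist(r$profile)),
                               names(r$profile))))
    else NULL)
}

#' Write a scenario to a JSON file
#'
#' @param spec a [scenario_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  jsonlite::write_json(scenario_to_plain(spec), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Load and validate a scenario JSON file
#'
#' Distributions whose sum deviates from 1 by at most 1e-6 are
#' renormalized; larger deviations are rejected with the offending chain
#' named. All validation problems are reported together. Unknown fields
#' produce a warning, not an error.
#'
#' @param path path to a scenario JSON file.
#' @return a validated [scenario_spec()].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path))
    stop("scenario file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  plain_to_scenario(raw, source = path)
}
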