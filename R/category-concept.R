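# Category concepts: categories situated in a context. A concept carries a
# stochastic frame, the split of its chains into context-independent and
# context-dependent ones, the probability threshold r of the
# statistical-consequence rule, and optional diagnosticity information
# (stipulated weights or declared contrast classes).

#' Category concept
#'
#' A category as used in a specific context. Its default inferences ("Cs
#' are normally V-A") are licensed by the statistical-consequence rule: a
#' feature V-A is a default iff P(V-A | C) is the unique maximum over A's
#' value space and exceeds the threshold `threshold_r`.
#'
#' @param name identifier.
#' @param frame a [stochastic_frame()] carrying the conditional
#'   distributions P(V-A | C).
#' @param context_independent chains active on all occasions (selection
#'   restrictions, animacy and the like).
#' @param context_dependent chains whose defaults are licensed by the
#'   embedding context (correlations in the scenario).
#' @param threshold_r probability threshold r, `0 <= r < 1`; strict
#'   inequality is used. Default 0.5.
#' @param diagnosticity optional stipulated attribute weights (named
#'   numeric, summing to 1); when present, [diagnosticity()] returns them
#'   verbatim instead of computing cue-validities.
#' @param contrasts optional list of contrast-class declarations, each a
#'   `list(name =, dist =)` where `dist` replaces distributions of the
#'   chains whose values license the context-dependent defaults.
#' @return object of class `category_concept`.
#' @export
category_concept <- function(name, frame,
                             context_independent = character(0),
                             context_dependent = character(0),
                             threshold_r = 0.5,
                             diagnosticity = NULL,
                             contrasts = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(frame, "stochastic_frame"))
  context_independent <- as.character(context_independent)
  context_dependent <- as.character(context_dependent)
  if (length(intersect(context_independent, context_dependent)))
    stop("chains cannot be both context-independent and context-dependent: ",
         paste(intersect(context_independent, context_dependent),
               collapse = ", "), call. = FALSE)
  declared <- c(context_independent, context_dependent)
  missing <- setdiff(declared, frame_chains(frame))
  if (length(missing))
    stop("declared chain(s) not defined in frame: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!is.numeric(threshold_r) || threshold_r < 0 || threshold_r >= 1)
    stop("`threshold_r` must lie in [0, 1)", call. = FALSE)
  if (!is.null(diagnosticity)) {
    check_distribution(diagnosticity, label = "stipulated diagnosticity")
    bad <- setdiff(names(diagnosticity), frame_chains(frame))
    if (length(bad))
      stop("diagnosticity weight on undefined chain(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(contrasts)) {
    stopifnot(is.list(contrasts))
    for (ct in contrasts) {
      if (is.null(ct$name) || is.null(ct$dist) || !is.list(ct$dist))
        stop("each contrast class needs `name` and `dist`", call. = FALSE)
      for (ch in names(ct$dist))
        check_distribution(ct$dist[[ch]],
                           label = paste0("contrast '", ct$name,
                                          "', chain '", ch, "'"))
    }
  }
  structure(list(name = name, frame = frame,
                 context_independent = context_independent,
                 context_dependent = context_dependent,
                 threshold_r = threshold_r,
                 diagnosticity = diagnosticity,
                 contrasts = contrasts),
            class = "category_concept")
}

#' @export
print.category_concept <- function(x, ...) {
  cat("<category_concept>", x$name, " (r =", x$threshold_r, ")\n")
  if (length(x$context_independent))
    cat("  context-independent:",
        paste(x$context_independent, collapse = ", "), "\n")
  if (length(x$context_dependent))
    cat("  context-dependent:  ",
        paste(x$context_dependent, collapse = ", "), "\n")
  om <- default_inferences(x)
  if (length(om))
    cat("  defaults:", paste(names(om), om, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Distribution of a chain within a concept; fixed chains without a stored
# value space yield a degenerate single-point vector.
concept_dist <- function(c, chain) {
  stopifnot(inherits(c, "category_concept"))
  if (chain %in% names(c$frame$dist)) return(c$frame$dist[[chain]])
  if (chain %in% names(c$frame$fixed))
    return(stats::setNames(1, c$frame$fixed[[chain]]))
  NULL
}

#' Conditional probability P(V-A | C)
#'
#' @param c a [category_concept()].
#' @param chain attribute chain.
#' @param value value label; a value outside the chain's stored space has
#'   probability 0.
#' @return probability.
#' @export
concept_prob <- function(c, chain, value) {
  p <- concept_dist(c, chain)
  if (is.null(p))
    stop("chain '", chain, "' undefined in concept '", c$name, "'",
         call. = FALSE)
  if (!value %in% names(p)) return(0)
  as.numeric(p[[value]])
}

#' Default inferences of a category concept (the set Omega)
#'
#' Applies the statistical-consequence rule to every declared chain
#' (context-independent and context-dependent): a feature is emitted iff
#' its probability is the unique maximum over the chain's value space and
#' strictly exceeds `r`. A tied maximum above the threshold means there is
#' no single normal value: no feature is emitted and a warning of class
#' `n400frames_tie` is signalled.
#'
#' @param c a [category_concept()].
#' @param r threshold override; defaults to the concept's `threshold_r`.
#' @return named character vector (chain -> default value).
#' @export
default_inferences <- function(c, r = c$threshold_r) {
  stopifnot(inherits(c, "category_concept"))
  out <- stats::setNames(character(0), character(0))
  for (ch in c(c$context_independent, c$context_dependent)) {
    p <- concept_dist(c, ch)
    pmax <- max(p)
    if (pmax <= r) next
    top <- which(p >= pmax - .prob_tol)
    if (length(top) > 1L) {
      warning(warningCondition(
        paste0("tied maximum on chain '", ch, "' of '", c$name,
               "': no default emitted"),
        class = "n400frames_tie"))
      next
    }
    out[ch] <- names(p)[top]
  }
  out
}

#' Membership status of a feature in a category concept
#'
#' @param c a [category_concept()].
#' @param chain,value the feature to test.
#' @return one of `"in"` (the feature is a default inference),
#'   `"negated_in"` (a rival value of the same chain is a default),
#'   `"undefined_attribute"` (the chain is not in the concept's signature),
#'   `"neither"`.
#' @export
is_member <- function(c, chain, value) {
  stopifnot(inherits(c, "category_concept"))
  if (!chain %in% frame_chains(c$frame)) return("undefined_attribute")
  omega <- default_inferences(c)
  if (chain %in% names(omega)) {
    if (identical(omega[[chain]], value)) return("in")
    return("negated_in")
  }
  "neither"
}

#' Prenominal evidence update
#'
#' Bottom-up evidence from a prenominal element (e.g. the adjective
#' "sweet"): the evidence feature's probability is forced to 1, and
#' correlated chains receive stipulated replacement distributions.
#'
#' @param chain,value the evidence feature.
#' @param revisions named list: chain -> replacement probability vector
#'   (each normalized).
#' @return object of class `prenominal_update`.
#' @export
prenominal_update <- function(chain, value, revisions = list()) {
  stopifnot(is.character(chain), length(chain) == 1L,
            is.character(value), length(value) == 1L)
  if (length(revisions)) {
    if (!is.list(revisions) || is.null(names(revisions)))
      stop("`revisions` must be a named list", call. = FALSE)
    for (ch in names(revisions))
      check_distribution(revisions[[ch]],
                         label = paste0("revision for chain '", ch, "'"))
  }
  structure(list(chain = chain, value = value, revisions = revisions),
            class = "prenominal_update")
}

#' Apply a prenominal update to a category concept
#'
#' Returns a new concept in which the evidence chain is degenerate at the
#' evidence value and every revised chain carries its replacement
#' distribution; all other chains are unchanged. Idempotent for a fixed
#' update.
#'
#' @param c a [category_concept()].
#' @param u a [prenominal_update()].
#' @return a new `category_concept`.
#' @export
apply_prenominal <- function(c, u) {
  stopifnot(inherits(c, "category_concept"), inherits(u, "prenominal_update"))
  dist <- c$frame$dist
  if (!u$chain %in% names(dist))
    stop("evidence chain '", u$chain, "' not present in concept '", c$name,
         "'", call. = FALSE)
  p <- dist[[u$chain]]
  if (!u$value %in% names(p))
    stop("evidence value '", u$value, "' not in value space of '", u$chain,
         "'", call. = FALSE)
  p[] <- 0
  p[[u$value]] <- 1
  dist[[u$chain]] <- p
  for (ch in names(u$revisions)) {
    if (!ch %in% names(dist))
      stop("revised chain '", ch, "' not present in concept", call. = FALSE)
    if (!setequal(names(u$revisions[[ch]]), names(dist[[ch]])))
      stop("revision for '", ch, "' does not cover its value space",
           call. = FALSE)
    dist[[ch]] <- u$revisions[[ch]][names(dist[[ch]])]
  }
  category_concept(c$name, stochastic_frame(c$frame$sort, dist, c$frame$fixed),
                   context_independent = c$context_independent,
                   context_dependent = c$context_dependent,
                   threshold_r = c$threshold_r,
                   diagnosticity = c$diagnosticity,
                   contrasts = c$contrasts)
}

#' Contrast classes of a category concept
#'
#' Contrast classes are sibling category concepts obtained by altering the
#' values of the chains whose correlations license the context-dependent
#' defaults. They are scenario data: each declared contrast supplies the
#' replacement distributions that hold under the alternative antecedent
#' value. With no declaration the list is empty and diagnosticity must be
#' stipulated.
#'
#' @param c a [category_concept()].
#' @return list of `category_concept` objects (possibly empty).
#' @export
contrast_classes <- function(c) {
  stopifnot(inherits(c, "category_concept"))
  if (is.null(c$contrasts) || !length(c$contrasts)) return(list())
  lapply(c$contrasts, function(ct) {
    dist <- c$frame$dist
    for (ch in names(ct$dist)) dist[[ch]] <- ct$dist[[ch]]
    category_concept(ct$name,
                     stochastic_frame(c$frame$sort, dist, c$frame$fixed),
                     context_independent = c$context_independent,
                     context_dependent = c$context_dependent,
                     threshold_r = c$threshold_r)
  })
}
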