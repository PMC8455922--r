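# Plausibility component: min-rule similarity of values, cue-validity and
# diagnosticity of attributes, and the typicality of the critical word's
# category relative to the argument concept.

#' Min-rule similarity of a feature between two concepts
#'
#' `sim(c1, c2 | V-A) = min(P(V-A | c1), P(V-A | c2))`: a feature is only
#' as similar as the *less* committed of the two concepts.
#'
#' @param c1,c2 [category_concept()] objects.
#' @param chain,value the feature.
#' @return probability.
#' @export
similarity <- function(c1, c2, chain, value) {
  min(concept_prob(c1, chain, value), concept_prob(c2, chain, value))
}

#' Cue-validity of a feature for a category
#'
#' The reversed conditional P(C | V-A) computed by Bayes' rule against the
#' contrast classes: `P(V-A|C) P(C) / sum_i P(V-A|C_i) P(C_i)` where the
#' classes are `c` followed by `contrasts`. Priors default to uniform. A
#' feature impossible in every class has undefined cue-validity; 0 is
#' returned with a warning.
#'
#' @param c a [category_concept()].
#' @param contrasts list of contrast [category_concept()]s (may be empty).
#' @param chain,value the feature.
#' @param priors optional numeric vector of priors over `c(list(c),
#'   contrasts)`; must sum to 1.
#' @return probability.
#' @export
cue_validity <- function(c, contrasts, chain, value, priors = NULL) {
  classes <- c(list(c), contrasts)
  k <- length(classes)
  if (is.null(priors)) priors <- rep(1 / k, k)
  if (length(priors) != k || abs(sum(priors) - 1) > .prob_tol)
    stop("`priors` must cover all ", k, " classes and sum to 1",
         call. = FALSE)
  lik <- vapply(classes, concept_prob, numeric(1), chain = chain,
                value = value)
  den <- sum(lik * priors)
  if (den <= 0) {
    warning("feature ", chain, "=", value,
            " impossible in every class; cue-validity undefined, returning 0")
    return(0)
  }
  lik[1] * priors[1] / den
}

#' Discriminative value d(C, A) of an attribute
#'
#' The maximum cue-validity of the attribute's values: a peak in the
#' reversed conditionals marks the attribute as discriminative for the
#' category against its contrast classes.
#'
#' @inheritParams cue_validity
#' @param chain the attribute chain.
#' @return probability.
#' @export
attribute_d <- function(c, contrasts, chain, priors = NULL) {
  p <- concept_dist(c, chain)
  if (is.null(p))
    stop("chain '", chain, "' undefined in concept '", c$name, "'",
         call. = FALSE)
  max(vapply(names(p), function(v)
    cue_validity(c, contrasts, chain, v, priors = priors), numeric(1)))
}

#' Diagnosticity profile of a category concept
#'
#' Per-attribute weights normalized to sum 1. When the concept stipulates
#' weights (scenario data) they are returned verbatim with
#' `source = "stipulated"`; otherwise the d-values against the concept's
#' contrast classes are computed and normalized (`source = "computed"`).
#'
#' @param c a [category_concept()].
#' @param contrasts contrast classes; defaults to [contrast_classes()] of
#'   `c`. Ignored for stipulated profiles.
#' @param chains attributes to weight; defaults to the concept's declared
#'   chains. Ignored for stipulated profiles.
#' @param priors optional priors over `c` and the contrasts.
#' @return object of class `diagnosticity_profile`: list with `weights`
#'   (named numeric summing to 1) and `source`.
#' @export
diagnosticity <- function(c, contrasts = NULL, chains = NULL, priors = NULL) {
  stopifnot(inherits(c, "category_concept"))
  if (!is.null(c$diagnosticity)) {
    return(structure(list(weights = c$diagnosticity, source = "stipulated"),
                     class = "diagnosticity_profile"))
  }
  if (is.null(contrasts)) contrasts <- contrast_classes(c)
  if (is.null(chains))
    chains <- c(c$context_independent, c$context_dependent)
  if (!length(chains))
    stop("no chains to weight", call. = FALSE)
  d <- vapply(chains, function(ch)
    attribute_d(c, contrasts, ch, priors = priors), numeric(1))
  if (all(d <= 0))
    stop("degenerate diagnosticity profile: all d-values are zero",
         call. = FALSE)
  structure(list(weights = d / sum(d), source = "computed"),
            class = "diagnosticity_profile")
}

#' @export
print.diagnosticity_profile <- function(x, ...) {
  cat("<diagnosticity_profile> (", x$source, ")\n", sep = "")
  print(round(x$weights, 4))
  invisible(x)
}

#' Typicality of the critical word's category relative to the argument
#' concept
#'
#' Raw typicality is the diagnosticity-weighted sum, over each profiled
#' attribute's full value space, of min-rule similarities:
#' `sum_j w_j sum_i min(P(V_i A_j | c_arg), P(V_i A_j | c_cw))`. It equals
#' 1 iff the profiled distributions coincide, and equals
#' `1 - sum_j w_j TV_j` for TV the total-variation distance.
#'
#' The normalized variant divides by the self-typicality of `c_arg`, with
#' inner sums restricted to `c_arg`'s default features only; this is the
#' variant on which a low-constraint context lowers the ceiling. The raw
#' variant is the one reproducing the worked birthday-party values and is
#' the default downstream.
#'
#' @param c_arg,c_cw [category_concept()] objects.
#' @param profile a [diagnosticity()] profile; defaults to
#'   `diagnosticity(c_arg)`.
#' @return object of class `typicality_report`: list with `per_feature`
#'   (data.frame: chain, value, diag, sim, product), `raw`, `normalized`,
#'   `profile`.
#' @export
typicality <- function(c_arg, c_cw, profile = NULL) {
  stopifnot(inherits(c_arg, "category_concept"),
            inherits(c_cw, "category_concept"))
  if (is.null(profile)) profile <- diagnosticity(c_arg)
  stopifnot(inherits(profile, "diagnosticity_profile"))
  w <- profile$weights
  undef <- setdiff(names(w), frame_chains(c_cw$frame))
  if (length(undef))
    stop("profiled chain(s) undefined in '", c_cw$name, "': ",
         paste(undef, collapse = ", "), call. = FALSE)
  rows <- list()
  raw <- 0
  for (ch in names(w)) {
    space <- names(concept_dist(c_arg, ch))
    sims <- vapply(space, function(v) similarity(c_arg, c_cw, ch, v),
                   numeric(1))
    rows[[ch]] <- data.frame(chain = ch, value = space,
                             diag = w[[ch]], sim = as.numeric(sims),
                             product = w[[ch]] * as.numeric(sims),
                             stringsAsFactors = FALSE, row.names = NULL)
    raw <- raw + w[[ch]] * sum(sims)
  }
  omega <- suppressWarnings(default_inferences(c_arg))
  restricted <- function(other) {
    tot <- 0
    for (ch in intersect(names(w), names(omega))) {
      v <- omega[[ch]]
      tot <- tot + w[[ch]] * similarity(c_arg, other, ch, v)
    }
    tot
  }
  den <- restricted(c_arg)
  normalized <- if (den > 0) restricted(c_cw) / den else NA_real_
  structure(list(per_feature = do.call(rbind, rows),
                 raw = raw, normalized = normalized, profile = profile),
            class = "typicality_report")
}

#' @export
print.typicality_report <- function(x, digits = 4, ...) {
  cat("<typicality_report> raw =", round(x$raw, digits),
      " normalized =", round(x$normalized, digits), "\n")
  df <- x$per_feature
  df$sim <- round(df$sim, digits)
  df$product <- round(df$product, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
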