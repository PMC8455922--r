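# Predictability component: surprisal, Shannon entropy over n-step frame
# extensions, and entropy reduction between the pre-critical-word frame
# (t1) and the post-update frame (t2).
#
# The log base defaults to 10 throughout; it is exposed as an argument and
# through run_config() but the worked values (0.433 etc.) are base-10.

#' Enumerate n-step frame extensions
#'
#' All complete value assignments to the given unfixed chains of `base`,
#' each weighted by its product-rule probability (per-chain conditionals
#' are treated as independent). Chains are limited to depth `n`; the total
#' number of extensions is capped.
#'
#' @param base a [stochastic_frame()].
#' @param chains chains to assign; must carry distributions in `base` and
#'   be unfixed. Empty set yields the single extension `base` itself with
#'   probability 1.
#' @param n maximum chain depth (default 3).
#' @param cap maximum number of extensions (default 1e5).
#' @return object of class `extension_set`: list with `base`,
#'   `assignments` (list of named character feature sets), `prob` (numeric
#'   vector summing to 1), `depth_n`.
#' @examples
#' f1 <- stochastic_frame("plant",
#'   dist = list(habitat = c(tropics = 0.9, moderate = 0.1),
#'               height  = c(tall = 0.6, small = 0.4)))
#' es <- enumerate_extensions(f1, c("habitat", "height"))
#' sort(es$prob)  # 0.04 0.06 0.36 0.54
#' @export
enumerate_extensions <- function(base, chains, n = 3, cap = 1e5) {
  stopifnot(inherits(base, "stochastic_frame"))
  chains <- as.character(chains)
  fs <- feature_set(base)
  bad <- chains[chains %in% names(fs)]
  if (length(bad))
    stop("chain(s) already fixed in base: ", paste(bad, collapse = ", "),
         call. = FALSE)
  deep <- chains[chain_depth(chains) > n]
  if (length(deep))
    stop("chain depth exceeds n = ", n, ": ", paste(deep, collapse = ", "),
         call. = FALSE)
  nodist <- setdiff(chains, names(base$dist))
  if (length(nodist))
    stop("chain(s) without a distribution in base: ",
         paste(nodist, collapse = ", "), call. = FALSE)
  if (!length(chains)) {
    return(structure(list(base = base,
                          assignments = list(stats::setNames(character(0),
                                                             character(0))),
                          prob = 1, depth_n = n),
                     class = "extension_set"))
  }
  spaces <- lapply(chains, function(ch) names(base$dist[[ch]]))
  size <- prod(lengths(spaces))
  if (size > cap)
    stop("extension product size ", size, " exceeds cap ", cap,
         call. = FALSE)
  grid <- expand.grid(stats::setNames(spaces, chains),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  assignments <- vector("list", nrow(grid))
  prob <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    asg <- stats::setNames(as.character(grid[i, ]), chains)
    p <- 1
    for (ch in chains) p <- p * base$dist[[ch]][[asg[[ch]]]]
    assignments[[i]] <- asg
    prob[i] <- p
  }
  structure(list(base = base, assignments = assignments, prob = prob,
                 depth_n = n),
            class = "extension_set")
}

#' Shannon entropy of a discrete distribution
#'
#' `-sum(p * log(p, base))` with the convention `0 * log 0 = 0`.
#'
#' @param p numeric vector of probabilities (need not be named).
#' @param base logarithm base; default 10 to match the model's worked
#'   values.
#' @return nonnegative real.
#' @export
shannon_entropy <- function(p, base = 10) {
  stopifnot(is.numeric(p), all(p >= -.prob_tol))
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log(p, base = base))
}

#' Entropy of an extension set
#'
#' @param es an [enumerate_extensions()] result.
#' @param base logarithm base (default 10).
#' @return Shannon entropy of the extension distribution.
#' @export
frame_entropy <- function(es, base = 10) {
  stopifnot(inherits(es, "extension_set"))
  shannon_entropy(es$prob, base = base)
}

#' Entropy reduction between two time points
#'
#' @param h1 entropy at t1 (before the critical word).
#' @param h2 entropy at t2 (after the update).
#' @return `h1 - h2`.
#' @export
entropy_reduction <- function(h1, h2) h1 - h2

#' Surprisal of an event
#'
#' @param p probability in \[0, 1\]; `p = 0` yields `Inf`.
#' @param base logarithm base (default 10).
#' @return nonnegative real (`-log(p)`).
#' @export
surprisal <- function(p, base = 10) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("`p` must be a single probability in [0, 1]", call. = FALSE)
  if (p == 0) return(Inf)
  -log(p, base = base)
}

#' Predictability component: entropies at t1 and t2 and their difference
#'
#' The t1 frame is the minimal frame closed under the argument concept's
#' context-independent default inferences; its open chains are the
#' context-dependent chains, over which extensions are enumerated. At t2
#' the confirmed *and* compatible features are treated as fixed (compatible
#' features can still be verified, so they count as information gained);
#' entropy is recomputed over the chains that remain open. Disconfirmed
#' chains stay open, so a fully disconfirming critical word yields zero
#' entropy reduction.
#'
#' @param c_arg the argument-position [category_concept()].
#' @param p the [update_set()] partition for the critical word (must not
#'   have failed).
#' @param n maximum chain depth (default 3).
#' @param base logarithm base (default 10).
#' @param cap extension-count cap passed to [enumerate_extensions()].
#' @return list with `h_t1`, `h_t2`, `delta_h`, and the open chain sets
#'   `open_t1`, `open_t2`.
#' @export
predictability_component <- function(c_arg, p, n = 3, base = 10, cap = 1e5) {
  stopifnot(inherits(c_arg, "category_concept"),
            inherits(p, "update_partition"))
  if (p$failed)
    stop("predictability_component called on a failed partition",
         call. = FALSE)
  fixed_t1 <- names(feature_set(c_arg$frame))
  open_t1 <- setdiff(c_arg$context_dependent, fixed_t1)
  h1 <- frame_entropy(enumerate_extensions(c_arg$frame, open_t1, n = n,
                                           cap = cap), base = base)
  gained <- intersect(c(names(p$confirmed), names(p$compatible)), open_t1)
  open_t2 <- setdiff(open_t1, gained)
  h2 <- frame_entropy(enumerate_extensions(c_arg$frame, open_t2, n = n,
                                           cap = cap), base = base)
  list(h_t1 = h1, h_t2 = h2, delta_h = entropy_reduction(h1, h2),
       open_t1 = open_t1, open_t2 = open_t2)
}
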