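# Core representation: sorted stochastic frames, attribute chains, feature
# sets (theta), and the information ordering between frames.

.prob_tol <- 1e-9

#' Sort hierarchy table
#'
#' Builds the sort signature of a scenario: a set of uniquely named sorts,
#' each with an optional parent (supercategory), e.g. tree below plant.
#' Parent links must be acyclic and resolve within the table.
#'
#' @param names character vector of sort names (unique).
#' @param parents character vector of parent sort names, `NA` for roots.
#' @return A `sort_table` (data.frame with columns `name`, `parent`).
#' @examples
#' sort_table(c("plant", "tree", "flower"), c(NA, "plant", "plant"))
#' @export
sort_table <- function(names, parents = rep(NA_character_, length(names))) {
  names <- as.character(names)
  parents <- as.character(parents)
  if (length(names) != length(parents))
    stop("`names` and `parents` must have equal length", call. = FALSE)
  if (anyDuplicated(names))
    stop("sort names must be unique", call. = FALSE)
  unresolved <- !is.na(parents) & !(parents %in% names)
  if (any(unresolved))
    stop("unresolved parent sort(s): ",
         paste(unique(parents[unresolved]), collapse = ", "), call. = FALSE)
  tab <- data.frame(name = names, parent = parents, stringsAsFactors = FALSE)
  for (nm in tab$name) {
    seen <- character(0)
    cur <- nm
    while (!is.na(cur)) {
      if (cur %in% seen)
        stop("cycle in sort hierarchy at '", cur, "'", call. = FALSE)
      seen <- c(seen, cur)
      cur <- tab$parent[match(cur, tab$name)]
    }
  }
  class(tab) <- c("sort_table", "data.frame")
  tab
}

#' Does one sort subsume another?
#'
#' `ancestor` subsumes `descendant` if they are equal or `ancestor` lies on
#' the parent chain of `descendant`.
#'
#' @param sorts a [sort_table()].
#' @param ancestor,descendant sort names present in `sorts`.
#' @return logical scalar.
#' @export
sort_subsumes <- function(sorts, ancestor, descendant) {
  stopifnot(inherits(sorts, "sort_table"))
  if (!all(c(ancestor, descendant) %in% sorts$name))
    stop("unknown sort(s): ",
         paste(setdiff(c(ancestor, descendant), sorts$name), collapse = ", "),
         call. = FALSE)
  cur <- descendant
  while (!is.na(cur)) {
    if (identical(cur, ancestor)) return(TRUE)
    cur <- sorts$parent[match(cur, sorts$name)]
  }
  FALSE
}

#' Attribute chain depth
#'
#' Chains are written with `.` separating segments, e.g. `"danger.location"`.
#'
#' @param chain character vector of chain names.
#' @return integer vector of segment counts.
#' @export
chain_depth <- function(chain) {
  lengths(strsplit(as.character(chain), ".", fixed = TRUE))
}

#' Construct a feature (value assigned to an attribute chain)
#'
#' Features are represented throughout the package as named character
#' vectors: names are attribute chains, elements are value labels. A
#' feature *set* is such a vector with unique names (at most one value per
#' chain).
#'
#' @param chain attribute chain name.
#' @param value value label.
#' @return length-1 named character vector.
#' @export
feature <- function(chain, value) {
  stats::setNames(as.character(value), as.character(chain))
}

check_distribution <- function(p, label = "distribution", tol = .prob_tol) {
  if (!is.numeric(p) || is.null(names(p)) || anyDuplicated(names(p)))
    stop(label, ": must be a named numeric vector with unique value labels",
         call. = FALSE)
  if (any(p < -tol) || any(p > 1 + tol))
    stop(label, ": probabilities outside [0, 1]", call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop(label, ": probabilities sum to ", format(sum(p)), ", not 1",
         call. = FALSE)
  invisible(p)
}

#' Stochastic frame
#'
#' A frame of a given sort in which each attribute chain is assigned its
#' finite value space together with a probability distribution on that
#' space. Observed (bottom-up) information is recorded in `fixed`: chains
#' whose value is known with probability 1. A chain may carry a degenerate
#' distribution (one value with probability 1) instead of an entry in
#' `fixed`; both count as fixed for [feature_set()].
#'
#' @param sort sort name of the frame.
#' @param dist named list: chain name -> named numeric probability vector
#'   over the chain's value space. Each vector must sum to 1 (within 1e-9).
#' @param fixed named character vector: chain name -> observed value.
#' @return An object of class `stochastic_frame`.
#' @examples
#' f <- stochastic_frame("plant",
#'   dist = list(habitat = c(tropics = 0.9, moderate = 0.1),
#'               height  = c(tall = 0.6, small = 0.4)))
#' feature_set(f)  # empty: nothing fixed yet
#' @export
stochastic_frame <- function(sort, dist = list(), fixed = character(0)) {
  stopifnot(is.character(sort), length(sort) == 1L)
  if (!is.list(dist) || (length(dist) && is.null(names(dist))))
    stop("`dist` must be a named list of probability vectors", call. = FALSE)
  for (ch in names(dist))
    check_distribution(dist[[ch]], label = paste0("chain '", ch, "'"))
  fixed <- if (length(fixed)) {
    stats::setNames(as.character(fixed), names(fixed))
  } else {
    stats::setNames(character(0), character(0))
  }
  if (length(fixed) && (is.null(names(fixed)) || anyDuplicated(names(fixed))))
    stop("`fixed` must be a named character vector with unique chains",
         call. = FALSE)
  both <- intersect(names(fixed), names(dist))
  for (ch in both) {
    p <- dist[[ch]]
    v <- fixed[[ch]]
    if (!v %in% names(p))
      stop("fixed value '", v, "' not in value space of chain '", ch, "'",
           call. = FALSE)
    if (p[[v]] < 1 - .prob_tol)
      stop("chain '", ch, "' is fixed but carries a non-degenerate ",
           "distribution", call. = FALSE)
  }
  structure(list(sort = sort, dist = dist, fixed = fixed),
            class = "stochastic_frame")
}

#' @export
print.stochastic_frame <- function(x, ...) {
  cat("<stochastic_frame> sort:", x$sort, "\n")
  fs <- feature_set(x)
  if (length(fs))
    cat("  fixed:", paste(names(fs), fs, sep = "=", collapse = ", "), "\n")
  open <- setdiff(names(x$dist), names(fs))
  for (ch in open)
    cat("  ", ch, ": ",
        paste(names(x$dist[[ch]]), format(x$dist[[ch]]), sep = "=",
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' All attribute chains defined in a frame
#' @param f a [stochastic_frame()].
#' @return character vector of chain names.
#' @export
frame_chains <- function(f) {
  stopifnot(inherits(f, "stochastic_frame"))
  union(names(f$dist), names(f$fixed))
}

#' The feature set theta(f) of a frame
#'
#' Returns every feature whose chain is fixed in the frame: chains listed
#' in `fixed` plus chains whose distribution is degenerate (one value at
#' probability 1, within tolerance).
#'
#' @param f a [stochastic_frame()].
#' @return named character vector (chain -> value); empty if nothing fixed.
#' @export
feature_set <- function(f) {
  stopifnot(inherits(f, "stochastic_frame"))
  out <- f$fixed
  for (ch in setdiff(names(f$dist), names(out))) {
    p <- f$dist[[ch]]
    i <- which(p >= 1 - .prob_tol)
    if (length(i) == 1L) out[ch] <- names(p)[i]
  }
  out
}

#' Information ordering on frames
#'
#' `subsumes(f1, f2)` is `TRUE` iff every chain defined in `f1` is defined
#' in `f2` and every fixed value of `f1` is fixed compatibly in `f2`
#' (identical atomic label, or the `f2` value lies below the `f1` value in
#' the sort hierarchy when one is supplied). The sorts of the two frames
#' must themselves be compatible: `f2`'s sort equal to or below `f1`'s.
#'
#' @param f1,f2 [stochastic_frame()] objects sharing a sort signature.
#' @param sorts optional [sort_table()] for sort-typed value subsumption;
#'   without it, value subsumption is label equality and the frame sorts
#'   must be identical.
#' @return logical scalar.
#' @export
subsumes <- function(f1, f2, sorts = NULL) {
  stopifnot(inherits(f1, "stochastic_frame"), inherits(f2, "stochastic_frame"))
  if (is.null(sorts)) {
    if (!identical(f1$sort, f2$sort))
      stop("incompatible sort signatures: '", f1$sort, "' vs '", f2$sort, "'",
           call. = FALSE)
  } else {
    if (!all(c(f1$sort, f2$sort) %in% sorts$name))
      stop("frame sort(s) missing from sort table", call. = FALSE)
    if (!sort_subsumes(sorts, f1$sort, f2$sort)) return(FALSE)
  }
  if (!all(frame_chains(f1) %in% frame_chains(f2))) return(FALSE)
  fs1 <- feature_set(f1)
  fs2 <- feature_set(f2)
  for (ch in names(fs1)) {
    if (!ch %in% names(fs2)) return(FALSE)
    v1 <- fs1[[ch]]
    v2 <- fs2[[ch]]
    ok <- identical(v1, v2) ||
      (!is.null(sorts) && all(c(v1, v2) %in% sorts$name) &&
         sort_subsumes(sorts, v1, v2))
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Fix a chain of a frame at a value
#'
#' Returns a new frame in which `chain` is observed at `value`
#' (the distribution, if any, becomes degenerate).
#'
#' @param f a [stochastic_frame()].
#' @param chain chain name.
#' @param value value label; must belong to the chain's value space when
#'   the chain carries a distribution.
#' @return a new `stochastic_frame`.
#' @export
fix_chain <- function(f, chain, value) {
  stopifnot(inherits(f, "stochastic_frame"))
  dist <- f$dist
  if (chain %in% names(dist)) {
    p <- dist[[chain]]
    if (!value %in% names(p))
      stop("value '", value, "' not in value space of chain '", chain, "'",
           call. = FALSE)
    p[] <- 0
    p[[value]] <- 1
    dist[[chain]] <- p
  }
  fixed <- f$fixed
  fixed[chain] <- value
  stochastic_frame(f$sort, dist = dist, fixed = fixed)
}

#' Probability of a frame extension under the product rule
#'
#' For `ext` an extension of `base` (see [subsumes()]), the probability of
#' `ext` given `base` is the product, over chains newly fixed in `ext`, of
#' `base`'s probability for the chosen value. Chains fixed in both frames
#' contribute nothing; a chain fixed in `ext` without a distribution in
#' `base` is an error. Independence across chains is assumed.
#'
#' @param base,ext [stochastic_frame()] objects with `subsumes(base, ext)`.
#' @param sorts optional [sort_table()] passed to [subsumes()].
#' @return probability in \[0, 1\].
#' @examples
#' f1 <- stochastic_frame("plant",
#'   dist = list(habitat = c(tropics = 0.9, moderate = 0.1),
#'               height  = c(tall = 0.6, small = 0.4)))
#' ftt <- fix_chain(fix_chain(f1, "habitat", "tropics"), "height", "tall")
#' extension_probability(f1, ftt)  # 0.54
#' @export
extension_probability <- function(base, ext, sorts = NULL) {
  if (!subsumes(base, ext, sorts = sorts))
    stop("`ext` is not an extension of `base`", call. = FALSE)
  fs_base <- feature_set(base)
  fs_ext <- feature_set(ext)
  new_chains <- setdiff(names(fs_ext), names(fs_base))
  p <- 1
  for (ch in new_chains) {
    if (!ch %in% names(base$dist))
      stop("chain '", ch, "' fixed in extension has no distribution in base",
           call. = FALSE)
    pv <- base$dist[[ch]][fs_ext[[ch]]]
    if (is.na(pv))
      stop("value '", fs_ext[[ch]], "' of chain '", ch,
           "' has no probability in base", call. = FALSE)
    p <- p * as.numeric(pv)
  }
  p
}
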