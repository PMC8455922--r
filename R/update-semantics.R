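# Combination of the argument-position concept with the critical word's
# category: the three-way feature partition (predictability side) and the
# resulting frame (plausibility side), including categorization failure.

new_update_partition <- function(confirmed = character(0),
                                 compatible = character(0),
                                 disconfirmed = character(0),
                                 failed = FALSE,
                                 failing_chains = character(0)) {
  empty <- stats::setNames(character(0), character(0))
  as_fs <- function(x) if (length(x)) x else empty
  structure(list(confirmed = as_fs(confirmed),
                 compatible = as_fs(compatible),
                 disconfirmed = as_fs(disconfirmed),
                 failed = failed,
                 failing_chains = as.character(failing_chains)),
            class = "update_partition")
}

#' @export
print.update_partition <- function(x, ...) {
  if (x$failed) {
    cat("<update_partition> FAILED on chain(s):",
        paste(x$failing_chains, collapse = ", "), "\n")
    return(invisible(x))
  }
  show <- function(lbl, fs)
    cat("  ", lbl, ": ",
        if (length(fs)) paste(names(fs), fs, sep = "=", collapse = ", ")
        else "(none)", "\n", sep = "")
  cat("<update_partition>\n")
  show("confirmed   ", x$confirmed)
  show("compatible  ", x$compatible)
  show("disconfirmed", x$disconfirmed)
  invisible(x)
}

#' Partition the argument concept's defaults against the critical word
#'
#' For each default inference V-A of `c_arg`: confirmed if V-A is also a
#' default of `c_cw`; disconfirmed if a rival value of the same chain is a
#' default of `c_cw`; compatible otherwise. The operation is partial: if
#' some chain carrying a default of `c_arg` is not defined at all for
#' `c_cw` (e.g. animacy attributes for "drawer"), categorization fails —
#' a modeled outcome, returned as `failed = TRUE` with the offending
#' chains, not an error.
#'
#' @param c_arg argument-position [category_concept()].
#' @param c_cw critical-word [category_concept()].
#' @return object of class `update_partition` with fields `confirmed`,
#'   `compatible`, `disconfirmed` (named character feature sets), `failed`,
#'   `failing_chains`.
#' @export
update_set <- function(c_arg, c_cw) {
  stopifnot(inherits(c_arg, "category_concept"),
            inherits(c_cw, "category_concept"))
  omega <- default_inferences(c_arg)
  missing <- setdiff(names(omega), frame_chains(c_cw$frame))
  if (length(missing))
    return(new_update_partition(failed = TRUE, failing_chains = missing))
  omega_cw <- default_inferences(c_cw)
  conf <- comp <- disc <- character(0)
  for (ch in names(omega)) {
    v <- omega[[ch]]
    if (ch %in% names(omega_cw)) {
      if (identical(omega_cw[[ch]], v)) conf[ch] <- v else disc[ch] <- v
    } else {
      comp[ch] <- v
    }
  }
  new_update_partition(conf, comp, disc)
}

#' Resulting frame of the second update step
#'
#' Builds the frame whose feature set is the confirmed features together
#' with, for each disconfirmed chain, the critical word's own default value
#' (the disconfirming feature). Compatible features are *not* carried over:
#' they are unverified at this stage.
#'
#' @param p an [update_set()] result with `failed = FALSE`.
#' @param c_arg,c_cw the two [category_concept()]s that produced `p`.
#' @return a [stochastic_frame()] of `c_arg`'s sort whose fixed features
#'   are exactly the confirmed plus disconfirming features.
#' @export
update_t <- function(p, c_arg, c_cw) {
  stopifnot(inherits(p, "update_partition"),
            inherits(c_arg, "category_concept"),
            inherits(c_cw, "category_concept"))
  if (p$failed)
    stop("update_t called on a failed partition", call. = FALSE)
  fixed <- p$confirmed
  if (length(p$disconfirmed)) {
    omega_cw <- default_inferences(c_cw)
    for (ch in names(p$disconfirmed)) fixed[ch] <- omega_cw[[ch]]
  }
  stochastic_frame(c_arg$frame$sort, dist = list(), fixed = fixed)
}
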