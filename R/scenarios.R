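# Scenario specifications: the serializable bundle of sorts, attributes,
# per-category conditional probability tables, the argument-position
# concept, prenominal updates, and critical words. Includes the worked
# fixtures and a seeded synthetic scenario generator.

#' Scenario specification
#'
#' Bundles everything needed to evaluate critical words in a context. The
#' object validates on construction; see [validate_scenario()] for the
#' individual checks.
#'
#' @param name scenario identifier.
#' @param sorts a [sort_table()] or list of `list(name, parent)` entries.
#' @param attributes named list: attribute name -> character vector of at
#'   least two distinct value labels.
#' @param categories named list: category name -> `list(sort,
#'   distributions)` with `distributions` a named list chain -> named
#'   probability vector over the attribute's value space.
#' @param arg_concept list describing the argument-position concept:
#'   `category` (name of its probability table in `categories`),
#'   `context_independent`, `context_dependent` (chain vectors),
#'   `threshold_r`, optional `diagnosticity` (stipulated weights),
#'   optional `contrasts` (list of `list(name, distributions)`), optional
#'   `provenance` notes.
#' @param prenominal_updates named list: update name -> `list(chain,
#'   value, revisions)`.
#' @param critical_words named list: word -> `list(category)`.
#' @param roles optional named list: role -> `list(weight, category,
#'   profile)` for the thematic-role extension.
#' @param constraint_level `"HC"` (high constraint) or `"LC"`.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, sorts, attributes, categories, arg_concept,
                          prenominal_updates = list(),
                          critical_words = list(),
                          roles = NULL,
                          constraint_level = "HC") {
  if (is.list(sorts) && !inherits(sorts, "sort_table")) {
    sorts <- sort_table(vapply(sorts, `[[`, character(1), "name"),
                        vapply(sorts, function(s) {
                          p <- s$parent
                          # JSON null round-trips as NULL or empty list
                          if (is.null(p) || !length(p)) NA_character_
                          else as.character(p)[[1]]
                        }, character(1)))
  }
  spec <- structure(list(format_version = 1L,
                         name = as.character(name),
                         constraint_level = constraint_level,
                         sorts = sorts,
                         attributes = attributes,
                         categories = categories,
                         arg_concept = arg_concept,
                         prenominal_updates = prenominal_updates,
                         critical_words = critical_words,
                         roles = roles),
                    class = "scenario_spec")
  issues <- validate_scenario(spec)
  if (length(issues))
    stop("invalid scenario '", name, "':\n  - ",
         paste(issues, collapse = "\n  - "), call. = FALSE)
  spec
}

#' Validate a scenario specification
#'
#' Collects every violation rather than stopping at the first, so a
#' malformed file produces an itemized report.
#'
#' @param spec a `scenario_spec` (or a structurally similar list).
#' @return character vector of problems; empty when valid.
#' @export
validate_scenario <- function(spec) {
  issues <- character(0)
  say <- function(...) issues <<- c(issues, paste0(...))
  if (!inherits(spec$sorts, "sort_table")) say("`sorts` is not a sort table")
  attrs <- spec$attributes
  if (!is.list(attrs) || is.null(names(attrs)) || anyDuplicated(names(attrs)))
    say("`attributes` must be a uniquely named list")
  for (a in names(attrs)) {
    vals <- attrs[[a]]
    if (length(vals) < 2L) say("attribute '", a, "': fewer than 2 values")
    if (anyDuplicated(vals)) say("attribute '", a, "': duplicate values")
  }
  check_dist_block <- function(dists, where) {
    if (!is.list(dists) || (length(dists) && is.null(names(dists)))) {
      say(where, ": `distributions` must be a named list")
      return(invisible(NULL))
    }
    for (ch in names(dists)) {
      p <- dists[[ch]]
      if (!ch %in% names(attrs)) {
        say(where, ": chain '", ch, "' is not a declared attribute")
        next
      }
      if (!is.numeric(p) || is.null(names(p))) {
        say(where, ", chain '", ch, "': not a named numeric vector")
        next
      }
      if (!setequal(names(p), attrs[[ch]]))
        say(where, ", chain '", ch, "': values do not match the ",
            "attribute's value space")
      if (any(p < 0) || any(p > 1))
        say(where, ", chain '", ch, "': probabilities outside [0, 1]")
      if (abs(sum(p) - 1) > .prob_tol)
        say(where, ", chain '", ch, "': probabilities sum to ",
            format(sum(p)), ", not 1")
    }
  }
  cats <- spec$categories
  if (!is.list(cats) || is.null(names(cats)) || anyDuplicated(names(cats)))
    say("`categories` must be a uniquely named list")
  for (cn in names(cats)) {
    cat_ <- cats[[cn]]
    if (inherits(spec$sorts, "sort_table") &&
        (is.null(cat_$sort) || !cat_$sort %in% spec$sorts$name))
      say("category '", cn, "': unknown sort '", cat_$sort, "'")
    check_dist_block(cat_$distributions, paste0("category '", cn, "'"))
  }
  arg <- spec$arg_concept
  if (is.null(arg$category) || !arg$category %in% names(cats)) {
    say("arg_concept: `category` must name an entry of `categories`")
  } else {
    arg_chains <- names(cats[[arg$category]]$distributions)
    ci <- as.character(arg$context_independent)
    cd <- as.character(arg$context_dependent)
    if (length(intersect(ci, cd)))
      say("arg_concept: chains both context-independent and -dependent: ",
          paste(intersect(ci, cd), collapse = ", "))
    undeclared <- setdiff(c(ci, cd), arg_chains)
    if (length(undeclared))
      say("arg_concept: chain(s) without a distribution: ",
          paste(undeclared, collapse = ", "))
    r <- arg$threshold_r
    if (is.null(r) || !is.numeric(r) || r < 0 || r >= 1)
      say("arg_concept: `threshold_r` must lie in [0, 1)")
    if (!is.null(arg$diagnosticity)) {
      w <- arg$diagnosticity
      if (!is.numeric(w) || is.null(names(w)) ||
          abs(sum(w) - 1) > .prob_tol)
        say("arg_concept: stipulated diagnosticity must be named and sum ",
            "to 1")
      else if (length(setdiff(names(w), arg_chains)))
        say("arg_concept: diagnosticity weight on undefined chain(s): ",
            paste(setdiff(names(w), arg_chains), collapse = ", "))
    }
    for (ct in arg$contrasts)
      check_dist_block(ct$distributions,
                       paste0("contrast '", ct$name, "'"))
    for (un in names(spec$prenominal_updates)) {
      u <- spec$prenominal_updates[[un]]
      if (is.null(u$chain) || !u$chain %in% arg_chains) {
        say("prenominal '", un, "': evidence chain not in arg concept")
      } else if (!is.null(attrs[[u$chain]]) &&
                 !u$value %in% attrs[[u$chain]]) {
        say("prenominal '", un, "': evidence value '", u$value,
            "' not in value space of '", u$chain, "'")
      }
      check_dist_block(u$revisions, paste0("prenominal '", un, "'"))
    }
  }
  if (length(spec$critical_words) &&
      (is.null(names(spec$critical_words)) ||
       anyDuplicated(names(spec$critical_words))))
    say("`critical_words` must be a uniquely named list")
  for (cw in names(spec$critical_words)) {
    ref <- spec$critical_words[[cw]]$category
    if (is.null(ref) || !ref %in% names(cats))
      say("critical word '", cw, "': unknown category '", ref, "'")
  }
  if (!is.null(spec$roles) && length(spec$roles)) {
    w <- vapply(spec$roles, function(r)
      if (is.numeric(r$weight)) r$weight else NA_real_, numeric(1))
    if (anyNA(w) || abs(sum(w) - 1) > .prob_tol)
      say("roles: role weights must be numeric and sum to 1")
    for (rn in names(spec$roles)) {
      role <- spec$roles[[rn]]
      if (is.null(role$category) || !role$category %in% names(cats))
        say("role '", rn, "': unknown category '", role$category, "'")
      if (!is.null(role$profile) &&
          (!is.numeric(role$profile) || is.null(names(role$profile)) ||
           abs(sum(role$profile) - 1) > .prob_tol))
        say("role '", rn, "': profile weights must be named and sum to 1")
    }
  }
  if (!spec$constraint_level %in% c("HC", "LC"))
    say("`constraint_level` must be \"HC\" or \"LC\"")
  issues
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$name, " [", x$constraint_level, "]\n")
  cat("  attributes:", paste(names(x$attributes), collapse = ", "), "\n")
  cat("  categories:", paste(names(x$categories), collapse = ", "), "\n")
  cat("  critical words:",
      paste(names(x$critical_words), collapse = ", "), "\n")
  if (length(x$prenominal_updates))
    cat("  prenominal updates:",
        paste(names(x$prenominal_updates), collapse = ", "), "\n")
  invisible(x)
}

# Build a category_concept for a named probability table of the scenario.
# For critical-word categories every chain is category-determined, i.e.
# context-independent.
build_concept <- function(spec, category, name = category,
                          context_independent = NULL,
                          context_dependent = character(0),
                          threshold_r = NULL,
                          diagnosticity = NULL, contrasts = NULL) {
  cat_ <- spec$categories[[category]]
  if (is.null(cat_))
    stop("unknown category '", category, "' in scenario '", spec$name, "'",
         call. = FALSE)
  if (is.null(context_independent))
    context_independent <- names(cat_$distributions)
  if (is.null(threshold_r))
    threshold_r <- spec$arg_concept$threshold_r
  category_concept(name,
                   stochastic_frame(cat_$sort, dist = cat_$distributions),
                   context_independent = context_independent,
                   context_dependent = context_dependent,
                   threshold_r = threshold_r,
                   diagnosticity = diagnosticity,
                   contrasts = contrasts)
}

#' Argument-position concept of a scenario
#'
#' @param spec a [scenario_spec()].
#' @param prenominal optional name of a prenominal update declared in the
#'   scenario, applied before returning.
#' @return a [category_concept()].
#' @export
scenario_arg_concept <- function(spec, prenominal = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  arg <- spec$arg_concept
  contrasts <- if (!is.null(arg$contrasts))
    lapply(arg$contrasts, function(ct)
      list(name = ct$name, dist = ct$distributions))
  cc <- build_concept(spec, arg$category, name = arg$category,
                      context_independent =
                        as.character(arg$context_independent),
                      context_dependent =
                        as.character(arg$context_dependent),
                      threshold_r = arg$threshold_r,
                      diagnosticity = arg$diagnosticity,
                      contrasts = contrasts)
  if (!is.null(prenominal)) {
    u <- spec$prenominal_updates[[prenominal]]
    if (is.null(u))
      stop("unknown prenominal update '", prenominal, "'; declared: ",
           paste(names(spec$prenominal_updates), collapse = ", "),
           call. = FALSE)
    cc <- apply_prenominal(cc, prenominal_update(u$chain, u$value,
                                                 u$revisions))
  }
  cc
}

#' Critical-word concept of a scenario
#'
#' @param spec a [scenario_spec()].
#' @param cw name of a declared critical word.
#' @return a [category_concept()]; all of its chains count as
#'   context-independent (category-determined defaults).
#' @export
scenario_cw_concept <- function(spec, cw) {
  stopifnot(inherits(spec, "scenario_spec"))
  entry <- spec$critical_words[[cw]]
  if (is.null(entry))
    stop("unknown critical word '", cw, "'; declared: ",
         paste(names(spec$critical_words), collapse = ", "), call. = FALSE)
  build_concept(spec, entry$category, name = cw)
}

# ---------------------------------------------------------------------------
# Worked fixtures. Probabilities marked "fixture-choice" in `provenance`
# are not printed in the source tables; they are package choices that
# reproduce the narrative orderings.

#' Holiday-resort scenario (planting along the driveway)
#'
#' A tropical-looking holiday resort where something was planted along the
#' driveway. The argument concept pre-activates habitat = tropics (0.9)
#' and height = tall (0.6); critical words are "palms" (best completion),
#' "pines" (confirms height, disconfirms habitat) and "tulips"
#' (disconfirms both). One contrast class varies the look antecedent to
#' moderate, giving habitat cue-validities 0.9 / 0.1 under equal priors.
#'
#' @return a [scenario_spec()].
#' @export
fixture_holiday_resort <- function() {
  scenario_spec(
    name = "holiday_resort",
    constraint_level = "HC",
    sorts = sort_table(c("plant", "tree", "flower"), c(NA, "plant", "plant")),
    attributes = list(habitat = c("tropics", "moderate"),
                      height = c("tall", "small")),
    categories = list(
      planting_theme = list(
        sort = "plant",
        distributions = list(habitat = c(tropics = 0.9, moderate = 0.1),
                             height = c(tall = 0.6, small = 0.4))),
      palm = list(
        sort = "tree",
        distributions = list(habitat = c(tropics = 0.9, moderate = 0.1),
                             height = c(tall = 0.8, small = 0.2))),
      pine = list(
        sort = "tree",
        distributions = list(habitat = c(tropics = 0.1, moderate = 0.9),
                             height = c(tall = 0.8, small = 0.2))),
      tulip = list(
        sort = "flower",
        distributions = list(habitat = c(tropics = 0.1, moderate = 0.9),
                             height = c(tall = 0.2, small = 0.8)))),
    arg_concept = list(
      category = "planting_theme",
      context_independent = character(0),
      context_dependent = c("habitat", "height"),
      threshold_r = 0.5,
      contrasts = list(list(
        name = "moderate_look",
        distributions = list(habitat = c(tropics = 0.1, moderate = 0.9)))),
      provenance = list(
        printed = c("planting_theme distributions",
                    "contrast habitat 0.1/0.9 (cue-validity 0.9/0.1)"),
        fixture_choice = c("palm/pine/tulip distributions"))),
    critical_words = list(palms = list(category = "palm"),
                          pines = list(category = "pine"),
                          tulips = list(category = "tulip")))
}

#' Birthday-party scenario (sweet/healthy cake/veggies)
#'
#' Dessert at a birthday party. The argument concept carries the printed
#' tables for taste, nutrition_value and served_at; prenominal "sweet" and
#' "healthy" updates revise them; critical words are "cake" and "veggies".
#' Diagnosticity is stipulated at 0.45 (taste), 0.1 (nutrition_value),
#' 0.45 (served_at).
#'
#' @return a [scenario_spec()].
#' @export
fixture_birthday_party <- function() {
  scenario_spec(
    name = "birthday_party",
    constraint_level = "HC",
    sorts = sort_table("food"),
    attributes = list(
      taste = c("sweet", "not_sweet"),
      nutrition_value = c("healthy", "not_healthy"),
      served_at = c("birthday_party", "not_birthday_party")),
    categories = list(
      dessert_arg = list(
        sort = "food",
        distributions = list(
          taste = c(sweet = 0.95, not_sweet = 0.05),
          nutrition_value = c(healthy = 0.05, not_healthy = 0.95),
          served_at = c(birthday_party = 0.98, not_birthday_party = 0.02))),
      cake = list(
        sort = "food",
        distributions = list(
          taste = c(sweet = 0.9, not_sweet = 0.1),
          nutrition_value = c(healthy = 0.2, not_healthy = 0.8),
          served_at = c(birthday_party = 0.98, not_birthday_party = 0.02))),
      veggies = list(
        sort = "food",
        distributions = list(
          taste = c(sweet = 0.2, not_sweet = 0.8),
          nutrition_value = c(healthy = 0.9, not_healthy = 0.1),
          served_at = c(birthday_party = 0.02, not_birthday_party = 0.98)))),
    arg_concept = list(
      category = "dessert_arg",
      context_independent = character(0),
      context_dependent = c("taste", "nutrition_value", "served_at"),
      threshold_r = 0.5,
      diagnosticity = c(taste = 0.45, nutrition_value = 0.1,
                        served_at = 0.45)),
    prenominal_updates = list(
      sweet = list(
        chain = "taste", value = "sweet",
        revisions = list(
          nutrition_value = c(healthy = 0.02, not_healthy = 0.98))),
      healthy = list(
        chain = "nutrition_value", value = "healthy",
        revisions = list(
          taste = c(sweet = 0.4, not_sweet = 0.6),
          served_at = c(birthday_party = 0.95,
                        not_birthday_party = 0.05)))),
    critical_words = list(cake = list(category = "cake"),
                          veggies = list(category = "veggies")))
}

#' Seaside-caution scenario (lifeguards cautioning ...)
#'
#' Lifeguards at the seaside caution a theme argument. Context-independent
#' chains are the animacy attributes (sentient, can_move) and in_danger;
#' in the high-constraint (HC) variant the shark context additionally
#' licenses the context-dependent chains location (= water) and afloat.
#' Critical words: "swimmers" (best completion), "trainees" (compatible on
#' the context-dependent chains: its location/afloat distributions are
#' flat, so no default is licensed either way), and "drawer", whose
#' category lacks the animacy chains and therefore triggers
#' categorization failure. All probabilities here are fixture choices
#' reproducing the narrative orderings; none are printed in the source.
#'
#' @param level `"HC"` or `"LC"`; LC drops the context-dependent chains
#'   from the argument concept, so fewer features are pre-activated.
#' @return a [scenario_spec()].
#' @export
fixture_seaside_caution <- function(level = c("HC", "LC")) {
  level <- match.arg(level)
  cd <- if (level == "HC") c("location", "afloat") else character(0)
  scenario_spec(
    name = paste0("seaside_caution_", level),
    constraint_level = level,
    sorts = sort_table(c("entity", "person", "object"),
                       c(NA, "entity", "entity")),
    attributes = list(
      sentient = c("yes", "no"),
      can_move = c("yes", "no"),
      in_danger = c("yes", "no"),
      location = c("water", "beach"),
      afloat = c("yes", "no")),
    categories = list(
      caution_theme = list(
        sort = "entity",
        distributions = list(
          sentient = c(yes = 0.95, no = 0.05),
          can_move = c(yes = 0.95, no = 0.05),
          in_danger = c(yes = 0.9, no = 0.1),
          location = c(water = 0.95, beach = 0.05),
          afloat = c(yes = 0.9, no = 0.1))),
      swimmer = list(
        sort = "person",
        distributions = list(
          sentient = c(yes = 0.99, no = 0.01),
          can_move = c(yes = 0.99, no = 0.01),
          in_danger = c(yes = 0.85, no = 0.15),
          location = c(water = 0.9, beach = 0.1),
          afloat = c(yes = 0.85, no = 0.15))),
      trainee = list(
        sort = "person",
        distributions = list(
          sentient = c(yes = 0.99, no = 0.01),
          can_move = c(yes = 0.99, no = 0.01),
          in_danger = c(yes = 0.6, no = 0.4),
          location = c(water = 0.5, beach = 0.5),
          afloat = c(yes = 0.5, no = 0.5))),
      drawer = list(
        sort = "object",
        distributions = list(
          location = c(water = 0.02, beach = 0.98),
          afloat = c(yes = 0.1, no = 0.9)))),
    arg_concept = list(
      category = "caution_theme",
      context_independent = c("sentient", "can_move", "in_danger"),
      context_dependent = cd,
      threshold_r = 0.5,
      contrasts = list(list(
        name = "danger_on_beach",
        distributions = list(location = c(water = 0.05, beach = 0.95),
                             afloat = c(yes = 0.1, no = 0.9)))),
      provenance = list(fixture_choice = "all probabilities")),
    critical_words = list(swimmers = list(category = "swimmer"),
                          trainees = list(category = "trainee"),
                          drawer = list(category = "drawer")))
}

# ---------------------------------------------------------------------------

# Draw a peaked distribution over `values`: a single maximum above the
# 0.5 threshold (uniform in [0.55, 0.95]) with the remainder split by a
# uniform Dirichlet. Emulates the worked tables, where every attribute has
# a clear normal value.
r_peaked_dist <- function(values, peak_value = sample(values, 1L)) {
  k <- length(values)
  peak <- stats::runif(1, 0.55, 0.95)
  rest <- stats::rexp(k - 1L)
  rest <- rest / sum(rest) * (1 - peak)
  p <- stats::setNames(numeric(k), values)
  p[peak_value] <- peak
  p[setdiff(values, peak_value)] <- rest
  p
}

#' Seeded synthetic scenario generator
#'
#' Generates a valid random scenario emulating the worked fixtures:
#' 2-4 attributes with 2-3 values each and peaked per-attribute
#' distributions (unique maximum in \[0.55, 0.95\], so every chain
#' licenses a default at r = 0.5). The first critical word shares the
#' argument concept's distributions exactly (best-completion control, so
#' its partition has no disconfirmed feature); when at least two critical
#' words are requested the second is forced to conflict on one
#' context-dependent chain (its peak is moved to a different value).
#' Deterministic for a fixed seed.
#'
#' @param seed integer seed.
#' @param n_attributes number of attributes, 2..4.
#' @param n_values values per attribute, 2..3.
#' @param n_cws number of critical words, 1..5.
#' @return a [scenario_spec()].
#' @export
generate_random_scenario <- function(seed, n_attributes = 3, n_values = 2,
                                     n_cws = 3) {
  stopifnot(n_attributes %in% 2:4, n_values %in% 2:3, n_cws %in% 1:5)
  set.seed(as.integer(seed))
  attr_names <- paste0("a", seq_len(n_attributes))
  attributes <- stats::setNames(
    lapply(attr_names, function(a) paste0(a, "_v", seq_len(n_values))),
    attr_names)
  arg_dist <- lapply(attributes, r_peaked_dist)
  ci <- attr_names[1L]
  cd <- attr_names[-1L]
  conflict_chain <- sample(cd, 1L)
  cats <- list(arg_category = list(sort = "thing",
                                   distributions = arg_dist))
  cws <- list()
  for (i in seq_len(n_cws)) {
    cn <- paste0("cat_cw", i)
    if (i == 1L) {
      dists <- arg_dist  # best completion: identical tables
    } else if (i == 2L) {
      dists <- lapply(attributes, r_peaked_dist)
      arg_peak <- names(which.max(arg_dist[[conflict_chain]]))
      other <- setdiff(attributes[[conflict_chain]], arg_peak)
      dists[[conflict_chain]] <-
        r_peaked_dist(attributes[[conflict_chain]],
                      peak_value = sample(other, 1L))
    } else {
      dists <- lapply(attributes, r_peaked_dist)
    }
    cats[[cn]] <- list(sort = "thing", distributions = dists)
    cws[[paste0("cw", i)]] <- list(category = cn)
  }
  w <- stats::rexp(n_attributes)
  scenario_spec(
    name = paste0("synthetic_", seed),
    constraint_level = "HC",
    sorts = sort_table("thing"),
    attributes = attributes,
    categories = cats,
    arg_concept = list(
      category = "arg_category",
      context_independent = ci,
      context_dependent = cd,
      threshold_r = 0.5,
      diagnosticity = stats::setNames(w / sum(w), attr_names),
      provenance = list(synthetic = TRUE, seed = as.integer(seed))),
    critical_words = cws)
}
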