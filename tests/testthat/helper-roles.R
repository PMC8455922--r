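# Synthetic prescription fixture for the thematic-role extension. The
# source materials print no probabilities for this example; every number
# here is a synthetic construction chosen to realize the qualitative
# plausibility ordering (see the roles test file).

role_concept <- function(name, dists) {
  category_concept(name, stochastic_frame("entity", dist = dists),
                   context_independent = names(dists))
}

prescription_roles <- function() {
  eq_profile <- function(chains)
    structure(list(weights = stats::setNames(rep(1 / length(chains),
                                                 length(chains)), chains),
                   source = "stipulated"),
              class = "diagnosticity_profile")
  actor_arg <- role_concept("actor_arg", list(
    animacy = c(animate = 0.99, inanimate = 0.01),
    domain = c(mental_health = 0.9, other = 0.1)))
  recipient_arg <- role_concept("recipient_arg", list(
    animacy = c(animate = 0.99, inanimate = 0.01),
    condition = c(mental = 0.9, other = 0.1)))
  medicine_arg <- role_concept("medicine_arg", list(
    animacy = c(animate = 0.01, inanimate = 0.99),
    form = c(pill = 0.9, other = 0.1)))
  list(
    # actor is the undischarged argument: highest role diagnosticity
    list(role = "actor", weight = 0.6, c_arg = actor_arg,
         profile = eq_profile(c("animacy", "domain"))),
    list(role = "recipient", weight = 0.3, c_arg = recipient_arg,
         profile = eq_profile(c("animacy", "condition"))),
    list(role = "medicine", weight = 0.1, c_arg = medicine_arg,
         profile = eq_profile(c("animacy", "form"))))
}

prescription_cws <- function() {
  list(
    psychiatrist = role_concept("psychiatrist", list(
      animacy = c(animate = 0.99, inanimate = 0.01),
      domain = c(mental_health = 0.9, other = 0.1),
      condition = c(mental = 0.05, other = 0.95))),
    schizophrenic = role_concept("schizophrenic", list(
      animacy = c(animate = 0.99, inanimate = 0.01),
      condition = c(mental = 0.95, other = 0.05))),
    guard = role_concept("guard", list(
      animacy = c(animate = 0.99, inanimate = 0.01),
      condition = c(mental = 0.05, other = 0.95))),
    pill = role_concept("pill", list(
      animacy = c(animate = 0.01, inanimate = 0.99),
      form = c(pill = 0.9, other = 0.1))),
    fence = role_concept("fence", list(
      animacy = c(animate = 0.01, inanimate = 0.99))))
}
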