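#' Stimulus-type conditions of the mouse-tracking Stroop design
#'
#' The design crosses colour words, colour-associated words, non-response-set
#' colour words and colour-neutral words with congruent or incongruent ink
#' colours, yielding six stimulus types. `colour-neutral` is the designated
#' reference level for all mixed models.
#'
#' @return Character vector of the six condition labels, ordered from the
#'   condition expected to show most interference to most facilitation.
#' @export
#' @examples
#' stroop_conditions()
stroop_conditions <- function() {
  c(
    "standard_incongruent",
    "nonresponse_set",
    "associated_incongruent",
    "neutral",
    "associated_congruent",
    "standard_congruent"
  )
}

#' @rdname stroop_conditions
#' @export
reference_condition <- function() "neutral"

#' Turn a character vector into the canonical condition factor
#'
#' @param x Character vector of condition labels.
#' @param reference Reference level placed first (dummy-coding baseline).
#' @return Factor with the six condition levels, reference first.
#' @export
condition_factor <- function(x, reference = reference_condition()) {
  bad <- setdiff(unique(x), stroop_conditions())
  if (length(bad) > 0) {
    abort(paste0("Unknown condition label(s): ", paste(bad, collapse = ", ")))
  }
  stats::relevel(factor(x, levels = stroop_conditions()), ref = reference)
}

#' The eight Stroop components as contrasts of condition marginal means
#'
#' Each component is the difference between two per-condition marginal means
#' (minuend minus subtrahend). The total congruency effect splits into
#' interference plus facilitation; interference splits further into response
#' conflict, semantic relevance and semantic conflict; facilitation splits
#' into response facilitation and semantic facilitation. These definitions
#' make the decomposition additive by construction (telescoping sums).
#'
#' @return Tibble with columns `component`, `minuend`, `subtrahend`, `parent`.
#' @export
#' @examples
#' component_table()
component_table <- function() {
  tibble::tribble(
    ~component,              ~minuend,                 ~subtrahend,              ~parent,
    "total_stroop",          "standard_incongruent",   "standard_congruent",     NA_character_,
    "interference",          "standard_incongruent",   "neutral",                "total_stroop",
    "facilitation",          "neutral",                "standard_congruent",     "total_stroop",
    "response_conflict",     "standard_incongruent",   "nonresponse_set",        "interference",
    "semantic_relevance",    "nonresponse_set",        "associated_incongruent", "interference",
    "semantic_conflict",     "associated_incongruent", "neutral",                "interference",
    "response_facilitation", "associated_congruent",   "standard_congruent",     "facilitation",
    "semantic_facilitation", "neutral",                "associated_congruent",   "facilitation"
  )
}

#' Contrast matrix of the eight components over the six condition means
#'
#' Rows are components, columns the six conditions; each row has a single +1
#' (minuend) and a single -1 (subtrahend), so `C %*% mu` evaluates all eight
#' components at once from a vector of condition means.
#'
#' @return Numeric matrix, 8 x 6, dimnames (component, condition).
#' @export
component_contrast_matrix <- function() {
  tab <- component_table()
  conds <- stroop_conditions()
  C <- matrix(0, nrow = nrow(tab), ncol = length(conds),
              dimnames = list(tab$component, conds))
  for (i in seq_len(nrow(tab))) {
    C[i, tab$minuend[i]] <- 1
    C[i, tab$subtrahend[i]] <- -1
  }
  C
}

#' Evaluate the eight Stroop components from per-condition means
#'
#' Pure contrast arithmetic: useful for ground-truth bookkeeping and for
#' checking additivity identities on any set of six condition means.
#'
#' @param means Named numeric vector of per-condition means; names must cover
#'   the six condition labels.
#' @return Tibble with `component` and `estimate`.
#' @export
#' @examples
#' components_from_means(c(
#'   standard_incongruent = 1189, nonresponse_set = 1111,
#'   associated_incongruent = 1075, neutral = 1070,
#'   associated_congruent = 1045, standard_congruent = 1029
#' ))
components_from_means <- function(means) {
  conds <- stroop_conditions()
  missing <- setdiff(conds, names(means))
  if (length(missing) > 0) {
    abort(paste0("`means` is missing condition(s): ", paste(missing, collapse = ", ")))
  }
  est <- drop(component_contrast_matrix() %*% means[conds])
  tibble::tibble(component = names(est), estimate = unname(est))
}

# Word/ink stimulus pairing used by the generator. Response-set colours come
# in two mirrored pairs (red-green, blue-yellow); every word is tied to one
# pair so the incorrect-response attractor is always the mirrored box.
stimulus_table <- function() {
  tibble::tribble(
    ~condition,               ~word,      ~word_colour, ~pair,
    "standard_incongruent",   "red",      "red",        "red_green",
    "standard_incongruent",   "green",    "green",      "red_green",
    "standard_incongruent",   "blue",     "blue",       "blue_yellow",
    "standard_incongruent",   "yellow",   "yellow",     "blue_yellow",
    "standard_congruent",     "red",      "red",        "red_green",
    "standard_congruent",     "green",    "green",      "red_green",
    "standard_congruent",     "blue",     "blue",       "blue_yellow",
    "standard_congruent",     "yellow",   "yellow",     "blue_yellow",
    "associated_incongruent", "tomato",   "red",        "red_green",
    "associated_incongruent", "salad",    "green",      "red_green",
    "associated_incongruent", "sky",      "blue",       "blue_yellow",
    "associated_incongruent", "corn",     "yellow",     "blue_yellow",
    "associated_congruent",   "tomato",   "red",        "red_green",
    "associated_congruent",   "salad",    "green",      "red_green",
    "associated_congruent",   "sky",      "blue",       "blue_yellow",
    "associated_congruent",   "corn",     "yellow",     "blue_yellow",
    "nonresponse_set",        "purple",   NA,           "red_green",
    "nonresponse_set",        "orange",   NA,           "red_green",
    "nonresponse_set",        "brown",    NA,           "blue_yellow",
    "nonresponse_set",        "grey",     NA,           "blue_yellow",
    "neutral",                "balcony",  NA,           "red_green",
    "neutral",                "dog",      NA,           "red_green",
    "neutral",                "bridge",   NA,           "blue_yellow",
    "neutral",                "cargo",    NA,           "blue_yellow"
  )
}

colour_pairs <- function() {
  list(red_green = c("red", "green"), blue_yellow = c("blue", "yellow"))
}

paired_colour <- function(colour) {
  map <- c(red = "green", green = "red", blue = "yellow", yellow = "blue")
  unname(map[colour])
}
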