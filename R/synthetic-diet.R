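#' Generate a synthetic diet-ingredient screen with planted strain responses
#'
#' Emulates a gnotobiotic diet-oscillation screen: a panel of diets, each a
#' random combination of complementary-food ingredient inclusion levels, fed
#' to a defined bacterial consortium. Each strain's log abundance is a linear
#' response (baseline plus planted ingredient slopes times inclusion level,
#' plus Gaussian noise) and the community is closed to relative abundances by
#' a softmax, so untargeted strains pick up the compositional echo of large
#' planted effects, as in real relative-abundance data.
#'
#' @param n_diets Number of diets (>= 3).
#' @param n_ingredients Number of ingredients.
#' @param n_strains Number of strains in the consortium.
#' @param planted_effects Data frame with columns `ingredient`, `strain`,
#'   `slope` giving the nonzero (ingredient, strain) response slopes on the
#'   log-abundance scale per unit inclusion level. May be empty (pure null).
#' @param noise_sd Gaussian noise SD on strain log abundance.
#' @param seed Integer seed.
#'
#' @return A list with `design` (tibble: `sample_id` plus one inclusion-level
#'   column per ingredient), `abundance` (tibble of strain relative
#'   abundances, rows sum to 1), `ground_truth` (the planted effects),
#'   and `degenerate_ingredients` (ingredients with a constant column in the
#'   realized design — flagged, not fatal).
#' @export
#' @examples
#' pe <- data.frame(ingredient = "ingredient_01", strain = "strain_01", slope = 3)
#' dd <- generate_diet_design(14, 12, 14, pe, seed = 3)
#' dd$design[1:3, 1:4]
generate_diet_design <- function(n_diets = 14, n_ingredients = 12,
                                 n_strains = 14,
                                 planted_effects = NULL, noise_sd = 0.5,
                                 seed = 1) {
  n_diets <- check_count(n_diets, "n_diets", min = 3)
  n_ingredients <- check_count(n_ingredients, "n_ingredients")
  n_strains <- check_count(n_strains, "n_strains")
  ingredients <- sprintf("ingredient_%02d", seq_len(n_ingredients))
  strains <- sprintf("strain_%02d", seq_len(n_strains))
  if (is.null(planted_effects)) {
    planted_effects <- tibble::tibble(ingredient = character(),
                                      strain = character(), slope = numeric())
  }
  planted_effects <- tibble::as_tibble(planted_effects)
  if (!all(c("ingredient", "strain", "slope") %in% names(planted_effects))) {
    abort("`planted_effects` needs columns ingredient, strain, slope",
          class = "gutmaturity_validation_error")
  }
  unknown <- setdiff(c(planted_effects$ingredient, planted_effects$strain),
                     c(ingredients, strains))
  if (length(unknown) > 0) {
    abort(paste0("planted effects reference unknown ids: ",
                 paste(unknown, collapse = ", ")),
          class = "gutmaturity_validation_error")
  }

  with_op_seed(seed, "diet_design", {
    levels <- matrix(runif(n_diets * n_ingredients), n_diets, n_ingredients,
                     dimnames = list(sprintf("diet_%02d", seq_len(n_diets)),
                                     ingredients))
    slopes <- matrix(0, n_ingredients, n_strains,
                     dimnames = list(ingredients, strains))
    if (nrow(planted_effects) > 0) {
      slopes[cbind(planted_effects$ingredient, planted_effects$strain)] <-
        planted_effects$slope
    }
    baseline <- rnorm(n_strains, 0, 0.5)
    logit <- sweep(levels %*% slopes, 2, baseline, "+") +
      matrix(rnorm(n_diets * n_strains, 0, noise_sd), n_diets, n_strains)
    abund <- t(apply(logit, 1, softmax))
    dimnames(abund) <- list(rownames(levels), strains)

    degenerate <- ingredients[apply(levels, 2, function(x) diff(range(x)) == 0)]
    if (length(degenerate) > 0) {
      warn(paste0("constant ingredient columns in design: ",
                  paste(degenerate, collapse = ", ")))
    }
    list(design = matrix_to_table(levels),
         abundance = matrix_to_table(abund),
         ground_truth = planted_effects,
         degenerate_ingredients = degenerate)
  })
}
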