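#' Define a test meal by macronutrient composition
#'
#' A meal is described by its carbohydrate, protein, fat and fiber masses in
#' grams. Energy is derived with the Atwater factors 4/4/9 kcal per gram of
#' carbohydrate/protein/fat; fiber contributes no energy and no insulin dose.
#'
#' @param name Meal label.
#' @param carb_g,protein_g,fat_g,fiber_g Macronutrient masses in grams
#'   (finite, non-negative).
#' @return An object of class `meal`.
#' @examples
#' meal("NPM", carb_g = 53, protein_g = 32, fat_g = 17, fiber_g = 0.05)
#' @export
meal <- function(name, carb_g, protein_g, fat_g, fiber_g = 0) {
  for (m in list(carb_g, protein_g, fat_g, fiber_g)) {
    if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 0) {
      stop("macronutrient masses must be single finite non-negative numbers",
           call. = FALSE)
    }
  }
  structure(
    list(name = as.character(name), carb_g = as.numeric(carb_g),
         protein_g = as.numeric(protein_g), fat_g = as.numeric(fat_g),
         fiber_g = as.numeric(fiber_g)),
    class = "meal"
  )
}

#' @export
print.meal <- function(x, ...) {
  cat(sprintf("Meal '%s': %.4g g carb, %.4g g protein, %.4g g fat, %.4g g fiber (%.0f kcal)\n",
              x$name, x$carb_g, x$protein_g, x$fat_g, x$fiber_g, meal_energy(x)))
  invisible(x)
}

#' Total meal energy (Atwater 4/4/9), kcal
#' @param m A [meal()].
#' @return Energy in kcal.
#' @export
meal_energy <- function(m) {
  stopifnot(inherits(m, "meal"))
  4 * m$carb_g + 4 * m$protein_g + 9 * m$fat_g
}

#' Energy from protein and fat, kcal
#'
#' The quantity counted by fat-protein-unit algorithms:
#' `4 * protein_g + 9 * fat_g`.
#'
#' @param m A [meal()].
#' @return Protein plus fat energy in kcal.
#' @export
protein_fat_energy <- function(m) {
  stopifnot(inherits(m, "meal"))
  4 * m$protein_g + 9 * m$fat_g
}

#' The two trial test meals
#'
#' Normal-protein meal (NPM): 53 g carbohydrate, 32 g protein, 17 g fat,
#' 0.05 g fiber. High protein-fat meal (HPFM): 35 g carbohydrate, 49 g
#' protein, 18.5 g fat, 0.04 g fiber. The two meals are isocaloric by design.
#'
#' @return A [meal()].
#' @export
npm_meal <- function() meal("NPM", carb_g = 53, protein_g = 32, fat_g = 17, fiber_g = 0.05)

#' @rdname npm_meal
#' @export
hpfm_meal <- function() meal("HPFM", carb_g = 35, protein_g = 49, fat_g = 18.5, fiber_g = 0.04)

#' Read meal definitions from a JSON config file
#'
#' The file holds either a single meal object or an array of them, each with
#' fields `name`, `carb_g`, `protein_g`, `fat_g` and optionally `fiber_g`
#' (grams).
#'
#' @param path Path to a JSON file.
#' @return A named list of [meal()] objects.
#' @export
read_meal_config <- function(path) {
  if (!file.exists(path)) stop("meal config not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(raw) == 0L) stop("empty meal config: ", path, call. = FALSE)
  if (!is.null(raw$name)) raw <- list(raw)  # single meal object
  meals <- lapply(raw, function(x) {
    need <- c("name", "carb_g", "protein_g", "fat_g")
    if (!all(need %in% names(x))) {
      stop("meal entry missing fields: ",
           paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
    }
    meal(x$name, x$carb_g, x$protein_g, x$fat_g,
         if (is.null(x$fiber_g)) 0 else x$fiber_g)
  })
  names(meals) <- vapply(meals, `[[`, "", "name")
  meals
}

#' Published mean mealtime doses for the four trial arms
#'
#' Reads the shipped fixture of arm-level mean insulin doses (units) actually
#' administered in the trial, used only for reporting arithmetic such as
#' [dose_increase_pct()]; the doses reflect per-subject ICRs and are not an
#' oracle for the bolus algorithms.
#'
#' @param path Fixture path; defaults to the copy installed with the package.
#' @return A data frame with columns `meal`, `algorithm`, `mean_dose_u`, `sd_u`.
#' @export
trial_mean_doses <- function(path = system.file("extdata", "table1_doses.json",
                                                package = "fpudose")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  data.frame(meal = raw$meal, algorithm = raw$algorithm,
             mean_dose_u = raw$mean_dose_u, sd_u = raw$sd_u)
}

#' Percentage dose increase of one mean dose over another
#'
#' `round(100 * (fpu_dose / cc_dose - 1))`, the whole-percent increase of the
#' fat-protein-unit arm's mean dose over the carbohydrate-counting arm's.
#'
#' @param fpu_dose,cc_dose Mean doses in insulin units; `cc_dose` must be > 0.
#' @return Whole-percent increase (integer-valued numeric).
#' @export
dose_increase_pct <- function(fpu_dose, cc_dose) {
  if (any(cc_dose <= 0)) stop("cc_dose must be positive", call. = FALSE)
  round_half_up(100 * (fpu_dose / cc_dose - 1))
}
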