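# Neonatal body composition, adiposity tertiles, and study-group assignment.

# coefficients of the validated flank-skinfold body-composition equation
.fm_coef <- c(intercept = 0.54657, birth_weight = 0.39055,
              skinfold = 0.0453, length = -0.03237)

#' Neonatal body composition from anthropometrics
#'
#' Fat mass (kg) is predicted by a validated linear equation in birth
#' weight (kg), flank skinfold (mm) and length (cm):
#' `FM = 0.39055 BW + 0.0453 SF - 0.03237 L + 0.54657`.
#' Lean (fat-free) mass is `BW - FM` and percentage body fat is
#' `FM / BW * 100`; both identities hold exactly in the output.
#'
#' @param birth_weight_kg birth weight in kg (> 0).
#' @param flank_skinfold_mm flank skinfold in mm.
#' @param length_cm neonatal length in cm.
#' @return data.frame with `fat_mass_kg`, `lean_mass_kg`, `pct_body_fat`.
#' @examples
#' body_composition(3.0, 5.0, 50.0)
#' @export
body_composition <- function(birth_weight_kg, flank_skinfold_mm, length_cm) {
  stopifnot_finite(birth_weight_kg, "birth_weight_kg")
  stopifnot_finite(flank_skinfold_mm, "flank_skinfold_mm")
  stopifnot_finite(length_cm, "length_cm")
  if (any(birth_weight_kg < 0))
    stop("birth weight must be non-negative")
  fm <- .fm_coef[["intercept"]] +
    .fm_coef[["birth_weight"]] * birth_weight_kg +
    .fm_coef[["skinfold"]] * flank_skinfold_mm +
    .fm_coef[["length"]] * length_cm
  pfat <- ifelse(birth_weight_kg > 0, fm / birth_weight_kg * 100, NA_real_)
  data.frame(fat_mass_kg = fm,
             lean_mass_kg = birth_weight_kg - fm,
             pct_body_fat = pfat)
}

#' Assign adiposity tertiles within one BMI category
#'
#' Samples are ranked on percentage body fat and split into the low (T1),
#' middle (T2) and high (T3) tertiles. T1 takes the lowest `ceiling(n/3)`
#' values and T3 the highest `floor(n/3)`, which makes the published group
#' sizes achievable at any n; ties are broken by stable sample-id order.
#' A fully degenerate input (all values equal) is labelled all-T2 with a
#' warning, since no adiposity ordering exists.
#'
#' @param pct_body_fat numeric vector of percentage body fat.
#' @param sample_ids identifiers used for stable tie-breaking
#'   (default: input order).
#' @return factor with levels T1, T2, T3 in the input order.
#' @export
assign_tertiles <- function(pct_body_fat, sample_ids = NULL) {
  n <- length(pct_body_fat)
  if (n < 3L) stop("need at least 3 samples to form tertiles")
  stopifnot_finite(pct_body_fat, "pct_body_fat")
  if (is.null(sample_ids)) sample_ids <- seq_len(n)
  lab <- rep("T2", n)
  if (length(unique(pct_body_fat)) == 1L) {
    warning("all pct_body_fat values equal; assigning all samples to T2")
  } else {
    ord <- order(pct_body_fat, sample_ids)
    n1 <- ceiling(n / 3)
    n3 <- floor(n / 3)
    lab[ord[seq_len(n1)]] <- "T1"
    lab[ord[(n - n3 + 1L):n]] <- "T3"
  }
  factor(lab, levels = c("T1", "T2", "T3"))
}

#' Assign maternal BMI category and study group
#'
#' Pregravid BMI 18-24.9 maps to the lean (LE) category and 30-40 to the
#' obese (OB) category (both bins closed at the printed endpoints); any
#' other BMI is EXCLUDED. The four study groups cross the BMI category
#' with the adiposity extreme tertiles: T1 is low adiposity (LA) and T3
#' high adiposity (HA); middle-tertile or excluded samples get study
#' group NONE.
#'
#' @param pregravid_bmi numeric vector of pregravid BMI.
#' @param adiposity_tertile factor/character of tertile labels (T1/T2/T3);
#'   NA allowed for samples excluded before tertile assignment.
#' @param sample_id optional identifiers carried into the output.
#' @return data.frame with `sample_id`, `bmi_category`, `adiposity_class`,
#'   `study_group`.
#' @export
assign_groups <- function(pregravid_bmi, adiposity_tertile,
                          sample_id = NULL) {
  if (any(is.na(pregravid_bmi))) stop("missing pregravid BMI")
  n <- length(pregravid_bmi)
  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(n))
  tert <- as.character(adiposity_tertile)
  bmi_cat <- ifelse(pregravid_bmi >= 18 & pregravid_bmi <= 24.9, "LE",
             ifelse(pregravid_bmi >= 30 & pregravid_bmi <= 40, "OB",
                    "EXCLUDED"))
  adip <- ifelse(is.na(tert), NA_character_,
          ifelse(tert == "T1", "LA", ifelse(tert == "T3", "HA", "MID")))
  grp <- ifelse(bmi_cat %in% c("LE", "OB") & adip %in% c("LA", "HA"),
                paste0(bmi_cat, adip), "NONE")
  data.frame(sample_id = sample_id,
             bmi_category = bmi_cat,
             adiposity_class = adip,
             study_group = grp,
             stringsAsFactors = FALSE)
}

#' Full cohort assignment from raw anthropometrics
#'
#' Convenience wrapper: computes body composition, assigns adiposity
#' tertiles of percentage body fat within each maternal BMI category, and
#' derives the four study groups.
#'
#' @param metadata data.frame with `sample_id`, `pregravid_bmi`,
#'   `birth_weight_kg`, `flank_skinfold_mm`, `length_cm`.
#' @return metadata with body-composition and group columns appended.
#' @export
cohort_assign <- function(metadata) {
  need <- c("sample_id", "pregravid_bmi", "birth_weight_kg",
            "flank_skinfold_mm", "length_cm")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  bc <- body_composition(metadata$birth_weight_kg,
                         metadata$flank_skinfold_mm,
                         metadata$length_cm)
  out <- cbind(metadata[setdiff(names(metadata), names(bc))], bc)
  bmi_cat <- ifelse(out$pregravid_bmi >= 18 & out$pregravid_bmi <= 24.9, "LE",
             ifelse(out$pregravid_bmi >= 30 & out$pregravid_bmi <= 40, "OB",
                    "EXCLUDED"))
  tert <- rep(NA_character_, nrow(out))
  for (cat in c("LE", "OB")) {
    idx <- which(bmi_cat == cat)
    if (length(idx) >= 3L)
      tert[idx] <- as.character(assign_tertiles(out$pct_body_fat[idx],
                                                out$sample_id[idx]))
  }
  grp <- assign_groups(out$pregravid_bmi, tert, out$sample_id)
  out$bmi_category <- grp$bmi_category
  out$adiposity_tertile <- tert
  out$adiposity_class <- grp$adiposity_class
  out$study_group <- grp$study_group
  out
}

#' Cohort summary table with two-way ANOVA, Tukey letters and Fisher tests
#'
#' Summarizes variables across the 2 x 2 design (maternal BMI category x
#' neonatal adiposity class). Continuous variables get per-cell mean and
#' SD, two-way ANOVA p-values for the maternal-obesity main effect, the
#' adiposity main effect and their interaction (partial, Type-III sums of
#' squares under sum-to-zero contrasts, appropriate for the unbalanced
#' design), and Tukey compact-letter groupings across the four cells.
#' Categorical variables get per-cell percentages and a Fisher exact p.
#'
#' Variables with no within-cell variance anywhere are flagged
#' (`note = "zero_within_cell_variance"`) and their ANOVA p-values set NA.
#'
#' @param metadata data.frame with `bmi_category` (LE/OB),
#'   `adiposity_class` (LA/HA) and the requested variables. Samples outside
#'   the four study cells are dropped.
#' @param variables character vector of continuous variable names.
#' @param categorical character vector of categorical variable names.
#' @return list with elements `continuous` (data.frame) and `categorical`
#'   (data.frame).
#' @export
cohort_table <- function(metadata, variables, categorical = character()) {
  keep <- metadata$bmi_category %in% c("LE", "OB") &
    metadata$adiposity_class %in% c("LA", "HA")
  md <- metadata[keep, , drop = FALSE]
  ob <- factor(md$bmi_category, levels = c("LE", "OB"))
  ha <- factor(md$adiposity_class, levels = c("LA", "HA"))
  cell <- factor(paste0(ob, ha), levels = c("LELA", "LEHA", "OBLA", "OBHA"))
  if (any(table(cell) == 0L)) stop("empty design cell")

  cont <- lapply(variables, function(v) {
    y <- md[[v]]
    ok <- is.finite(y)
    row <- list(variable = v)
    for (cl in levels(cell)) {
      yy <- y[ok & cell == cl]
      row[[paste0(cl, "_n")]] <- length(yy)
      row[[paste0(cl, "_mean")]] <- mean(yy)
      row[[paste0(cl, "_sd")]] <- stats::sd(yy)
    }
    within_var <- tapply(y[ok], cell[ok], stats::var)
    if (all(within_var == 0 | is.na(within_var))) {
      row$p_ob <- NA_real_; row$p_ha <- NA_real_; row$p_interaction <- NA_real_
      row$tukey_letters <- NA_character_
      row$note <- "zero_within_cell_variance"
    } else {
      old <- options(contrasts = c("contr.sum", "contr.poly"))
      on.exit(options(old), add = TRUE)
      fit <- stats::lm(y[ok] ~ ob[ok] * ha[ok])
      d1 <- stats::drop1(fit, ~ ., test = "F")  # Type-III partial SS
      pv <- d1[["Pr(>F)"]]
      row$p_ob <- pv[2]; row$p_ha <- pv[3]; row$p_interaction <- pv[4]
      row$tukey_letters <- paste(tukey_letters(y[ok], cell[ok]),
                                 collapse = "/")
      row$note <- ""
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  cont <- do.call(rbind, cont)

  cat_rows <- lapply(categorical, function(v) {
    x <- factor(md[[v]])
    tab <- table(cell, x)
    p <- stats::fisher.test(tab)$p.value
    row <- list(variable = v)
    for (cl in levels(cell)) {
      n <- sum(cell == cl)
      row[[paste0(cl, "_pct")]] <-
        paste(sprintf("%s:%.0f%%", colnames(tab), 100 * tab[cl, ] / n),
              collapse = " ")
    }
    row$p_fisher <- p
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  categorical_df <- if (length(cat_rows)) do.call(rbind, cat_rows) else
    data.frame()

  list(continuous = cont, categorical = categorical_df)
}

# Tukey HSD compact-letter display across the 4 design cells.
#' @keywords internal
tukey_letters <- function(y, cell) {
  fit <- stats::aov(y ~ cell, data = data.frame(y = y, cell = cell))
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(cell = "Tukey"))
  cld <- multcomp::cld(glht)
  letters <- cld$mcletters$Letters
  toupper(letters[levels(cell)])
}
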