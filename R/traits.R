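#' Metabolic body weight
#'
#' Body weight scaled to metabolic size, `bw^0.75` (kg^0.75); feed intake
#' in this pipeline is expressed per unit metabolic weight.
#'
#' @param bw_kg Body weight in kg (> 0).
#' @return Metabolic weight in kg^0.75.
#' @export
metabolic_weight <- function(bw_kg) {
  if (any(is.na(bw_kg)) || any(bw_kg <= 0))
    stop("metabolic_weight: body weight must be positive", call. = FALSE)
  bw_kg^0.75
}

#' 3.5% fat-corrected milk yield
#'
#' Gaines-type linear standardization of milk yield to 3.5% fat:
#' `FCM = (0.432 + 0.1625 * fat%) * milk yield`. The formula is linear in
#' yield, so the result carries whatever volume/mass unit the yield is in.
#'
#' @param milk_kg_day Milk yield (kg/day, or any linear unit), >= 0.
#' @param fat_pct Milk fat percentage, >= 0.
#' @return Fat-corrected yield in the unit of `milk_kg_day`.
#' @export
fcm35 <- function(milk_kg_day, fat_pct) {
  if (any(is.na(milk_kg_day)) || any(milk_kg_day < 0))
    stop("fcm35: milk yield must be non-negative", call. = FALSE)
  if (any(is.na(fat_pct)) || any(fat_pct < 0))
    stop("fcm35: fat percentage must be non-negative", call. = FALSE)
  (0.432 + 0.1625 * fat_pct) * milk_kg_day
}

#' Net energy secreted in milk (NRC equation)
#'
#' `Milk NE (Mcal NE_L/day) = milk yield (kg/d) * (0.0929*fat% +
#' 0.0563*protein% + 0.0395*lactose%)`.
#'
#' @param milk_kg_day Milk yield in kg/day, >= 0.
#' @param fat_pct,protein_pct,lactose_pct Milk composition, percent, >= 0.
#' @return Mcal NE_L per day.
#' @export
milk_net_energy <- function(milk_kg_day, fat_pct, protein_pct, lactose_pct) {
  comp <- cbind(milk_kg_day, fat_pct, protein_pct, lactose_pct)
  if (any(is.na(comp)) || any(comp < 0))
    stop("milk_net_energy: all components must be non-negative",
         call. = FALSE)
  milk_kg_day * (0.0929 * fat_pct + 0.0563 * protein_pct +
                   0.0395 * lactose_pct)
}

#' Predicted enteric methane yield from rumen propionate
#'
#' Regression prediction `methane (g/kg DMI) = 316 / propionate + 4.4`,
#' with propionate in mM. The curve is convex and decreasing: low-
#' propionate (acetate-dominated) fermentation predicts high methane.
#'
#' @param propionate_mM Rumen propionate concentration in mM (> 0).
#' @return Predicted methane yield in g per kg dry-matter intake.
#' @export
predicted_methane <- function(propionate_mM) {
  if (any(is.na(propionate_mM)) || any(propionate_mM <= 0))
    stop("predicted_methane: propionate must be positive", call. = FALSE)
  316 / propionate_mM + 4.4
}

#' Derive the feed-efficiency trait table from animal records
#'
#' Resolves dry-matter intake (an explicit `dmi_kg_day` column wins;
#' otherwise `dmi_kg_day = dmi_g_per_mbw * bw^0.75 / 1000`), converts milk
#' volume to mass at density 1.0 g/ml, and computes per animal:
#' metabolic weight, FCM 3.5%, gross FE (kg milk / kg DMI), adjusted FE
#' (kg FCM / kg DMI), milk net energy (Mcal/day), FE for lactation
#' (Mcal milk NE / kg DMI), and predicted methane when propionate is
#' present.
#'
#' @param records Data frame of animal records: `animal_id`, `breed`,
#'   `bw_kg`, `milk_ml_day`, `fat_pct`, `protein_pct`, `lactose_pct`, and
#'   at least one of `dmi_kg_day` / `dmi_g_per_mbw`; optional
#'   `propionate_mM`.
#' @return Data frame (class `trait_table`) with one row per animal:
#'   animal_id, breed, mbw_kg075, dmi_kg_day, milk_kg_day, fcm35_kg_day,
#'   gross_fe, adjusted_fe, milk_ne, fe_lactation, methane_g_per_kg_dmi.
#' @export
derive_traits <- function(records) {
  req <- c("animal_id", "bw_kg", "milk_ml_day", "fat_pct", "protein_pct",
           "lactose_pct")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("derive_traits: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(records$dmi_kg_day) && is.null(records$dmi_g_per_mbw))
    stop("derive_traits: need dmi_kg_day or dmi_g_per_mbw", call. = FALSE)
  if (any(records$milk_ml_day < 0))
    stop("derive_traits: milk yield must be non-negative", call. = FALSE)
  pct <- records[c("fat_pct", "protein_pct", "lactose_pct")]
  if (any(pct < 0) || any(pct > 100))
    stop("derive_traits: percentages must lie in [0, 100]", call. = FALSE)
  mbw <- metabolic_weight(records$bw_kg)
  dmi <- records$dmi_kg_day
  if (is.null(dmi)) {
    dmi <- records$dmi_g_per_mbw * mbw / 1000
  } else if (!is.null(records$dmi_g_per_mbw)) {
    dmi <- ifelse(is.na(dmi), records$dmi_g_per_mbw * mbw / 1000, dmi)
  }
  if (any(is.na(dmi)) || any(dmi <= 0))
    stop("derive_traits: dry-matter intake must be positive for every animal",
         call. = FALSE)
  milk_kg <- records$milk_ml_day / 1000  # density 1.0 g/ml
  fcm <- fcm35(milk_kg, records$fat_pct)
  ne <- milk_net_energy(milk_kg, records$fat_pct, records$protein_pct,
                        records$lactose_pct)
  out <- data.frame(
    animal_id = records$animal_id,
    breed = if (is.null(records$breed)) NA_character_ else records$breed,
    mbw_kg075 = mbw,
    dmi_kg_day = dmi,
    milk_kg_day = milk_kg,
    fcm35_kg_day = fcm,
    gross_fe = milk_kg / dmi,
    adjusted_fe = fcm / dmi,
    milk_ne = ne,
    fe_lactation = ne / dmi,
    stringsAsFactors = FALSE
  )
  if (!is.null(records$propionate_mM))
    out$methane_g_per_kg_dmi <- predicted_methane(records$propionate_mM)
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Two-group summary of derived traits
#'
#' Per-animal traits are averaged within group and compared with an
#' unpaired t-test (Student's pooled-variance test by default; Welch by
#' flag). Columns with zero pooled within-group variance are flagged and
#' get NA test statistics rather than an infinite t.
#'
#' @param traits A `trait_table` (or any data.frame of numeric trait
#'   columns plus a grouping column).
#' @param group_col Name of the grouping column (default "breed"); must
#'   take exactly two levels with >= 2 animals each.
#' @param welch Use Welch's unequal-variance t-test instead of the pooled
#'   test.
#' @return Data frame with one row per trait: group means, standard
#'   errors, mean difference, t statistic, p-value, and a
#'   `zero_within_variance` flag.
#' @export
group_summary <- function(traits, group_col = "breed", welch = FALSE) {
  if (!group_col %in% names(traits))
    stop("group_summary: no column '", group_col, "'", call. = FALSE)
  g <- factor(traits[[group_col]])
  if (nlevels(g) != 2)
    stop("group_summary: grouping column must have exactly two levels",
         call. = FALSE)
  if (any(table(g) < 2))
    stop("group_summary: each group needs at least 2 animals", call. = FALSE)
  num <- vapply(traits, is.numeric, logical(1))
  num[group_col] <- FALSE
  lv <- levels(g)
  rows <- lapply(names(traits)[num], function(tr) {
    x <- traits[[tr]][g == lv[1]]
    y <- traits[[tr]][g == lv[2]]
    zero_var <- stats::var(x) == 0 && stats::var(y) == 0
    if (zero_var) {
      tt <- list(statistic = NA_real_, p.value = NA_real_)
    } else {
      tt <- stats::t.test(x, y, var.equal = !welch)
    }
    data.frame(
      trait = tr,
      mean_1 = mean(x), se_1 = stats::sd(x) / sqrt(length(x)),
      mean_2 = mean(y), se_2 = stats::sd(y) / sqrt(length(y)),
      mean_diff = mean(x) - mean(y),
      t = unname(tt$statistic), p_value = tt$p.value,
      zero_within_variance = zero_var,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  names(out)[c(2, 3, 4, 5)] <- c(paste0("mean_", lv[1]), paste0("se_", lv[1]),
                                 paste0("mean_", lv[2]), paste0("se_", lv[2]))
  rownames(out) <- NULL
  out
}
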