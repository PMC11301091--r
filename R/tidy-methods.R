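# broom-style tidiers for the package's result objects.

#' Tidy an editome summary
#'
#' @param x An `editome_summary` object.
#' @param ... Unused.
#' @return The substitution-type fraction table as a tibble.
#' @export
tidy.editome_summary <- function(x, ...) {
  x$substitutions
}

#' @rdname tidy.editome_summary
#' @export
glance.editome_summary <- function(x, ...) {
  ag <- x$substitutions$fraction[x$substitutions$sub == "A>G"]
  tibble(n_sites = x$n_sites,
         n_substitution_types = nrow(x$substitutions),
         atog_fraction = if (length(ag) == 0L) 0 else ag)
}

#' Tidy a diet enrichment table
#'
#' @param x A `diet_enrichment` object.
#' @param ... Unused.
#' @return A tibble with one row per comparison.
#' @export
tidy.diet_enrichment <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Tidy a directional expansion test
#'
#' @param x An `og_direction_test` object.
#' @param ... Unused.
#' @return The per-OG result tibble.
#' @export
tidy.og_direction_test <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname tidy.og_direction_test
#' @export
glance.og_direction_test <- function(x, ...) {
  bind_cols(count_directional_significant(x),
            tibble(fraction_pred_higher = sum(x$direction == "pred_higher") / nrow(x)))
}

#' Tidy an LD contrast
#'
#' @param x An `ld_contrast` object.
#' @param ... Unused.
#' @return The per-pair r-squared tibble.
#' @export
tidy.ld_contrast <- function(x, ...) {
  x$pairs
}

#' @rdname tidy.ld_contrast
#' @export
glance.ld_contrast <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$medians, names_from = "pair_type",
                             values_from = c("n_pairs", "median_r2"))
  bind_cols(wide, tibble(p_value = x$p_value))
}

#' Tidy an intra/inter OG identity contrast
#'
#' @param x An `og_identity_contrast` object.
#' @param ... Unused.
#' @return A tibble stacking the intra (per OG) and inter (per bin) means.
#' @export
tidy.og_identity_contrast <- function(x, ...) {
  bind_rows(
    mutate(x$intra, set = "intra", unit = .data$og_id) |> select("set", "unit", "mean_identity"),
    mutate(x$inter, set = "inter", unit = paste0("bin", .data$bin)) |>
      select("set", "unit", "mean_identity")
  )
}

#' @rdname tidy.og_identity_contrast
#' @export
glance.og_identity_contrast <- function(x, ...) {
  tibble(n_ogs = nrow(x$intra), n_bins = nrow(x$inter),
         intra_mean = mean(x$intra$mean_identity),
         inter_mean = mean(x$inter$mean_identity),
         p_value = x$p_value)
}
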