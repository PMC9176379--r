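# Composition metrics: OFF/OLF, DXA mass fractions, site-to-region averaging.

#' Anatomical site and region vocabulary
#'
#' Ten measurement sites map onto four general anatomical regions:
#' biceps = \{BS, BL\}, abdomen = \{LL, LR, UL, UR\},
#' quadriceps = \{VL, RF\}, calf = \{GM, GL\}.
#'
#' @format A named character vector: names are site codes, values regions.
#' @export
site_regions <- c(BS = "biceps", BL = "biceps",
                  LL = "abdomen", LR = "abdomen",
                  UL = "abdomen", UR = "abdomen",
                  VL = "quadriceps", RF = "quadriceps",
                  GM = "calf", GL = "calf")

#' @rdname site_regions
#' @export
region_names <- c("biceps", "abdomen", "quadriceps", "calf")

off_fields <- function(x) {
  if (inherits(x, "chromophore_set")) {
    list(thbmb = x$thbmb, water = x$water, fat = x$fat)
  } else if (is.data.frame(x)) {
    need <- c("thbmb", "water", "fat")
    if (!all(need %in% names(x))) {
      stop("need columns thbmb, water, fat", call. = FALSE)
    }
    list(thbmb = x$thbmb, water = x$water, fat = x$fat)
  } else {
    stop("expected a chromophore_set or a data.frame", call. = FALSE)
  }
}

# guard against obviously mis-scaled inputs (e.g. heme in M or nM, fractions
# 0-1 instead of percent) before forming the deliberately mixed-unit ratio
off_unit_guard <- function(f) {
  if (any(f$water > 100 + 1e-9) || any(f$fat > 100 + 1e-9) ||
      any(f$thbmb > 1000)) {
    stop("OFF/OLF expect THbMb in uM (0 to ~200), water and fat in percent ",
         "(0-100); inputs look mis-scaled", call. = FALSE)
  }
  if (any(f$thbmb < 0) || any(f$water < 0) || any(f$fat < 0)) {
    stop("negative concentrations", call. = FALSE)
  }
  invisible(f)
}

#' Optical fat fraction (OFF) and optical lean fraction (OLF)
#'
#' OFF = 100 * fat / (THbMb + water + fat);
#' OLF = 100 * (THbMb + water) / (THbMb + water + fat) = 100 - OFF.
#' The ratio deliberately mixes units — THbMb in uM (typical tissue range
#' 0 to ~200) with water and fat in percent — because those scales are
#' commensurate in mixed biological tissue; a unit guard rejects inputs
#' that look mis-scaled.
#'
#' @param x a \code{chromophore_set} (possibly vectorized) or a data.frame
#'   with columns \code{thbmb}, \code{water}, \code{fat}
#' @param scale \code{"percent"} (default, 0-100) or \code{"fraction"}
#'   (0-1)
#' @return numeric vector of OFF (or OLF) values
#' @examples
#' compute_off(chromophore_set(thbmb = 19.4, sto2 = 63, water = 11.3, fat = 67.3))
#' @export
compute_off <- function(x, scale = c("percent", "fraction")) {
  scale <- match.arg(scale)
  f <- off_unit_guard(off_fields(x))
  denom <- f$thbmb + f$water + f$fat
  if (any(denom <= 0)) {
    stop("OFF undefined: THbMb + water + fat must be positive", call. = FALSE)
  }
  off <- f$fat / denom
  if (scale == "percent") 100 * off else off
}

#' @rdname compute_off
#' @export
compute_olf <- function(x, scale = c("percent", "fraction")) {
  scale <- match.arg(scale)
  full <- if (scale == "percent") 100 else 1
  full - compute_off(x, scale = scale)
}

#' DXA three-compartment mass fractions
#'
#' Converts fat, lean-soft-tissue and bone masses to percentages of total
#' body mass. The three fractions sum to 100 exactly.
#'
#' @param fat_mass,lst_mass,bone_mass masses in kg, >= 0 (vectorized)
#' @return data.frame with columns \code{fat_pct}, \code{lst_pct},
#'   \code{bone_pct}
#' @export
dxa_fractions <- function(fat_mass, lst_mass, bone_mass) {
  if (any(c(fat_mass, lst_mass, bone_mass) < 0)) {
    stop("masses must be non-negative", call. = FALSE)
  }
  total <- fat_mass + lst_mass + bone_mass
  if (any(total <= 0)) stop("total mass must be positive", call. = FALSE)
  data.frame(fat_pct = 100 * fat_mass / total,
             lst_pct = 100 * lst_mass / total,
             bone_pct = 100 * bone_mass / total)
}

site_table_columns <- c("participant_id", "site", "replicate",
                        "hbmbo2", "hbmbr", "water", "fat",
                        "a500", "b_power")

check_site_table <- function(sites) {
  miss <- setdiff(site_table_columns, names(sites))
  if (length(miss)) {
    stop("site table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(sites$site), names(site_regions))
  if (length(bad)) {
    stop("unknown site codes: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(sites)
}

#' Aggregate site replicates into a regional summary
#'
#' Averages the replicate measurements within each site, then averages the
#' sites belonging to the region, field-wise on the chromophore and
#' scattering parameters. OFF and OLF are computed from the region-averaged
#' chromophores (not averaged over per-site metrics) unless
#' \code{metric_mode = "mean_of_metrics"}.
#'
#' @param sites data.frame of per-replicate site measurements with columns
#'   \code{participant_id}, \code{site}, \code{replicate}, \code{hbmbo2},
#'   \code{hbmbr}, \code{water}, \code{fat}, \code{a500}, \code{b_power}
#' @param region one of \code{region_names}; rows from other regions raise
#'   an error unless \code{strict = FALSE}, in which case they are dropped
#' @param metric_mode \code{"metrics_of_mean"} (default) or
#'   \code{"mean_of_metrics"}
#' @param strict reject rows from foreign regions (default TRUE)
#' @return data.frame, one row per participant, with averaged chromophore
#'   and scattering fields plus derived \code{thbmb}, \code{sto2},
#'   \code{mus800}, \code{off}, \code{olf} and \code{region}
#' @export
aggregate_region <- function(sites, region,
                             metric_mode = c("metrics_of_mean",
                                             "mean_of_metrics"),
                             strict = TRUE) {
  metric_mode <- match.arg(metric_mode)
  region <- match.arg(region, region_names)
  check_site_table(sites)
  member <- names(site_regions)[site_regions == region]
  foreign <- setdiff(unique(sites$site), member)
  if (length(foreign)) {
    if (strict) {
      stop("sites not in region '", region, "': ",
           paste(foreign, collapse = ", "), call. = FALSE)
    }
    sites <- sites[sites$site %in% member, , drop = FALSE]
  }
  if (nrow(sites) == 0L) stop("no sites for region '", region, "'",
                              call. = FALSE)
  num <- c("hbmbo2", "hbmbr", "water", "fat", "a500", "b_power")
  # replicate mean within site, then site mean within region
  site_means <- stats::aggregate(sites[num],
                                 by = sites[c("participant_id", "site")],
                                 FUN = mean)
  reg <- stats::aggregate(site_means[num],
                          by = site_means["participant_id"], FUN = mean)
  reg$thbmb <- reg$hbmbo2 + reg$hbmbr
  reg$sto2 <- ifelse(reg$thbmb > 0, 100 * reg$hbmbo2 / reg$thbmb, NA_real_)
  reg$mus800 <- reg$a500 * (800 / 500)^(-reg$b_power)
  if (metric_mode == "metrics_of_mean") {
    reg$off <- compute_off(reg)
    reg$olf <- 100 - reg$off
  } else {
    sm <- site_means
    sm$thbmb <- sm$hbmbo2 + sm$hbmbr
    sm$off <- compute_off(sm)
    per <- stats::aggregate(sm["off"], by = sm["participant_id"], FUN = mean)
    reg$off <- per$off[match(reg$participant_id, per$participant_id)]
    reg$olf <- 100 - reg$off
  }
  reg$region <- region
  reg[order(reg$participant_id), , drop = FALSE]
}

#' Regional summaries for all four anatomical regions
#'
#' @param sites per-replicate site table (see \code{aggregate_region})
#' @param ... passed to \code{aggregate_region}
#' @return data.frame stacking the four regional summaries
#' @export
summarize_regions <- function(sites, ...) {
  check_site_table(sites)
  out <- lapply(region_names, function(r) {
    aggregate_region(sites[site_regions[sites$site] == r, , drop = FALSE],
                     r, ...)
  })
  do.call(rbind, out)
}
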