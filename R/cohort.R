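# Synthetic case/control laboratory cohorts ----------------------------------
#
# Emulates a clinical study population: an ovarian-cancer case group and three
# control subgroups (other malignant tumors, benign disease, healthy physical
# examination), each row carrying a 25-indicator laboratory panel plus three
# demographic fields.  Indicators follow a 3-latent-factor model
# (tumor-marker/hormone, glucose-lipid metabolism, inflammation) so that a
# correlation PCA finds three dominant components, and case/control group-mean
# directions are controlled per indicator.

#' Default 25-indicator roster
#'
#' The laboratory panel, grouped by category: tumor markers (CA125, CA15-3,
#' CA72-4, CA19-9, CEA, AFP, SF, SSC), blood-cell parameters (NLR, PLR, RDW),
#' coagulation (Fib, DD), sex hormones (beta-HCG, E2, P, LH, FSH),
#' biochemistry (AGR, PA, CRP, FPG) and lipid metabolism (TG, TC,
#' LDL-C/HDL-C).
#'
#' @return Character vector of 25 indicator names.
#' @export
default_indicators <- function() {
  c("CA125", "CA15-3", "CA72-4", "CA19-9", "CEA", "AFP", "SF", "SSC",
    "NLR", "PLR", "RDW", "Fib", "DD", "beta-HCG", "E2", "P", "LH", "FSH",
    "AGR", "PA", "CRP", "FPG", "TG", "TC", "LDL-C/HDL-C")
}

# indicators whose mean is lower in cases than controls
.neg_direction <- c("E2", "P", "AGR", "PA", "TC")

default_factor_loadings <- function(indicators = default_indicators()) {
  L <- matrix(0, length(indicators), 3,
              dimnames = list(indicators,
                              c("tumor_hormone", "glucose_lipid", "inflammation")))
  f1 <- c("CA125", "CA15-3", "CA72-4", "SF", "RDW", "Fib", "E2", "P", "AGR")
  f2 <- c("PLR", "FSH", "FPG", "TG")
  f3 <- c("CRP", "LDL-C/HDL-C", "NLR")
  L[intersect(f1, indicators), 1] <- 0.8
  L[intersect(f2, indicators), 2] <- 0.8
  L[intersect(f3, indicators), 3] <- 0.8
  L
}

#' Cohort specification
#'
#' @param n_cases Number of case rows (default 185).
#' @param n_controls_by_subgroup Three counts for the control subgroups
#'   `(other_malignant, benign, healthy)` (default `c(138, 339, 92)`).
#' @param indicator_names Indicator roster; default [default_indicators()].
#' @param latent_factor_loadings Numeric matrix `length(indicators) x 3`
#'   mapping indicators to the three latent factors; row names must match the
#'   roster.
#' @param case_effect_directions Named vector of `+1/-1` per indicator; the
#'   default is `-1` exactly for E2, P, AGR, PA and TC and `+1` elsewhere.
#' @param case_effect_size Magnitude of the case mean shift in
#'   standard-deviation units; scalar or per-indicator named vector. The
#'   default is 0.8 everywhere except CA125 (1.5), so the single-marker CA125
#'   baseline is informative but clearly weaker than the full panel.
#' @param noise_sd Residual (non-factor) standard deviation; scalar or
#'   per-indicator.
#' @param subgroup_effect_scale Fractions of the case shift applied to the
#'   tumor-marker indicators of each control subgroup, making the
#'   other-malignant subgroup the hardest to separate.
#' @param seed Integer seed.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_cases = 185L,
                        n_controls_by_subgroup = c(other_malignant = 138L,
                                                   benign = 339L,
                                                   healthy = 92L),
                        indicator_names = default_indicators(),
                        latent_factor_loadings = NULL,
                        case_effect_directions = NULL,
                        case_effect_size = NULL,
                        noise_sd = 0.6,
                        subgroup_effect_scale = c(other_malignant = 0.3,
                                                  benign = 0.1,
                                                  healthy = 0),
                        seed = 1L) {
  if (length(n_controls_by_subgroup) != 3L)
    stop("`n_controls_by_subgroup` needs 3 counts", call. = FALSE)
  if (any(c(n_cases, n_controls_by_subgroup) < 0))
    stop("group sizes must be nonnegative", call. = FALSE)
  p <- length(indicator_names)
  if (is.null(latent_factor_loadings))
    latent_factor_loadings <- default_factor_loadings(indicator_names)
  if (!all(rownames(latent_factor_loadings) %in% indicator_names) ||
      nrow(latent_factor_loadings) != p) {
    bad <- setdiff(rownames(latent_factor_loadings), indicator_names)
    stop("loadings name unknown indicator(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  latent_factor_loadings <- latent_factor_loadings[indicator_names, , drop = FALSE]
  if (is.null(case_effect_directions)) {
    case_effect_directions <- stats::setNames(rep(1, p), indicator_names)
    case_effect_directions[intersect(.neg_direction, indicator_names)] <- -1
  }
  if (is.null(case_effect_size)) {
    case_effect_size <- stats::setNames(rep(0.8, p), indicator_names)
    if ("CA125" %in% indicator_names) case_effect_size["CA125"] <- 1.5
  } else if (length(case_effect_size) == 1L) {
    case_effect_size <- stats::setNames(rep(case_effect_size, p), indicator_names)
  }
  if (length(noise_sd) == 1L) noise_sd <- stats::setNames(rep(noise_sd, p), indicator_names)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls_by_subgroup = stats::setNames(
                   as.integer(n_controls_by_subgroup),
                   c("other_malignant", "benign", "healthy")),
                 indicator_names = indicator_names,
                 latent_factor_loadings = latent_factor_loadings,
                 case_effect_directions = case_effect_directions[indicator_names],
                 case_effect_size = case_effect_size[indicator_names],
                 noise_sd = noise_sd[indicator_names],
                 subgroup_effect_scale = subgroup_effect_scale,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d cases / %s controls, %d indicators, seed %d\n",
              x$n_cases, paste(x$n_controls_by_subgroup, collapse = "+"),
              length(x$indicator_names), x$seed))
  invisible(x)
}

#' Generate a synthetic case/control cohort
#'
#' Each indicator value is `baseline + effect + loadings %*% factors + noise`
#' with three standard-normal latent factors per subject. Cases receive a mean
#' shift of `case_effect_directions * case_effect_size`; control subgroups
#' receive a scaled-down shift on the tumor-marker indicators only.
#' Demographics are drawn independently: age uniform on published study
#' ranges (cases 16-83, other malignant 27-85, benign 18-80, healthy 20-84),
#' menopausal status Bernoulli with probability rising past age 50, and
#' pregnancies Poisson (mean 1.2 for cases, 1.6 for controls, reflecting
#' parity as a protective factor).
#'
#' @param spec A [cohort_spec()].
#' @return A data frame (the cohort table) with 25 indicator columns plus
#'   `age`, `menopausal`, `pregnancies`, `label` (`"case"`/`"control"`) and
#'   `subgroup` (`"case"`, `"other_malignant"`, `"benign"`, `"healthy"`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- length(spec$indicator_names)
  groups <- c(case = spec$n_cases, spec$n_controls_by_subgroup)
  tumor_markers <- intersect(
    c("CA125", "CA15-3", "CA72-4", "CA19-9", "CEA", "AFP", "SF", "SSC"),
    spec$indicator_names)
  age_range <- list(case = c(16, 83), other_malignant = c(27, 85),
                    benign = c(18, 80), healthy = c(20, 84))
  preg_mean <- c(case = 1.2, other_malignant = 1.6, benign = 1.6, healthy = 1.6)
  case_shift <- spec$case_effect_directions * spec$case_effect_size

  with_seed(spec$seed, {
    blocks <- lapply(names(groups), function(g) {
      n <- groups[[g]]
      if (n == 0L) return(NULL)
      shift <- if (g == "case") case_shift else {
        s <- stats::setNames(numeric(p), spec$indicator_names)
        s[tumor_markers] <- spec$subgroup_effect_scale[[g]] * case_shift[tumor_markers]
        s
      }
      fac <- matrix(rnorm(n * 3), n, 3)
      eps <- matrix(rnorm(n * p), n, p) * rep(spec$noise_sd, each = n)
      X <- matrix(shift, n, p, byrow = TRUE) +
        fac %*% t(spec$latent_factor_loadings) + eps
      colnames(X) <- spec$indicator_names
      age <- round(runif(n, age_range[[g]][1], age_range[[g]][2]))
      menop <- rbinom(n, 1, stats::plogis((age - 50) / 3))
      preg <- rpois(n, preg_mean[[g]])
      df <- as.data.frame(X, check.names = FALSE)
      df$age <- age
      df$menopausal <- menop
      df$pregnancies <- preg
      df$label <- if (g == "case") "case" else "control"
      df$subgroup <- g
      df
    })
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out
  })
}

#' Write / read a cohort table as CSV
#'
#' Column order is fixed: the 25 indicators, then `age`, `menopausal`,
#' `pregnancies`, `label`, `subgroup`.
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly (`write_cohort_csv`); the cohort data frame
#'   (`read_cohort_csv`).
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Per-indicator group-mean profile
#'
#' Compares case and control means for every indicator, mirroring a heat-map
#' comparison of average indicator levels between groups.
#'
#' @param cohort Cohort data frame with `label` column.
#' @param indicators Indicator columns to profile; defaults to every column
#'   before `age` that is numeric.
#' @return Data frame with `indicator`, `case_mean`, `control_mean`,
#'   `direction` (sign of case minus control).
#' @export
group_mean_profile <- function(cohort, indicators = NULL) {
  if (is.null(indicators)) {
    stop_at <- match("age", names(cohort), nomatch = ncol(cohort) + 1L)
    indicators <- names(cohort)[seq_len(stop_at - 1L)]
  }
  cases <- cohort$label == "case"
  if (!any(cases) || all(cases)) stop("both groups must be nonempty", call. = FALSE)
  cm <- colMeans(cohort[cases, indicators, drop = FALSE])
  km <- colMeans(cohort[!cases, indicators, drop = FALSE])
  data.frame(indicator = indicators, case_mean = as.numeric(cm),
             control_mean = as.numeric(km),
             direction = sign(as.numeric(cm) - as.numeric(km)),
             stringsAsFactors = FALSE)
}
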