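# Synthetic fixture generator.  Emits all four template dialects with known
# ground truth so that every downstream module can be exercised, and its
# parameter-recovery properties tested, without any external data.  The
# canned specifications emulate the study designs of typical certification
# campaigns (see the methods vignette); all shipped data are synthetic.

#' Build a fixture specification
#'
#' Defines the ground truth of a synthetic certification campaign: analyte
#' grand means, between/within-bottle dispersion of the homogeneity study,
#' between/within-laboratory dispersion and planted outlier laboratories of
#' the collaborative study, drift and noise of the classical stability
#' series, Arrhenius parameters of the accelerated study, and drift of the
#' post-certification monitoring series.  All dispersion parameters are
#' relative percentages of the analyte mean unless stated otherwise.
#'
#' @param analytes tibble with columns `name`, `unit`, `mean`.
#' @param homogeneity list: `n_bottles`, `n_reps`, `s_bb_rel` (%),
#'   `s_wb_rel` (%).
#' @param certification list: `n_labs`, `n_reps`, `sigma_lab_rel` (%),
#'   `sigma_rep_rel` (%), `outlier_mean` (named shifts of lab means in units
#'   of the between-lab SD), `outlier_sd` (named within-lab SD inflation
#'   factors).
#' @param stability list: `n_dates`, `step_days`, `slope_rel_per_month`
#'   (%/month), `noise_rel` (%), `start_date`.
#' @param arrhenius list: `reference_temperature` (degC), `temperatures`
#'   (stressed levels, degC), `time_points` (months), `n_rep`, `Ea_kJ_mol`,
#'   `k_ref_per_month` (rate at `T_ref`), `T_ref` (degC), `noise_ln_sd`,
#'   `n_reference`, `start_date`.
#' @param lts list: `n_points`, `step_months`, `drift_per_month` (absolute),
#'   `noise_abs`, `uncertainty_value`, `uncertainty_definition`,
#'   `certification_date`.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(analytes, homogeneity = NULL, certification = NULL,
                         stability = NULL, arrhenius = NULL, lts = NULL) {
  stopifnot(is.data.frame(analytes),
            all(c("name", "unit", "mean") %in% names(analytes)))
  sds <- c(homogeneity$s_bb_rel, homogeneity$s_wb_rel,
           certification$sigma_lab_rel, certification$sigma_rep_rel,
           stability$noise_rel, arrhenius$noise_ln_sd, lts$noise_abs)
  if (any(sds < 0)) stop_validation("dispersion parameters must be non-negative")
  structure(list(analytes = as_tibble(analytes), homogeneity = homogeneity,
                 certification = certification, stability = stability,
                 arrhenius = arrhenius, lts = lts),
            class = "fixture_spec")
}

#' Canned fixture: soil trace-metal certification campaign (synthetic)
#'
#' Emulates the design of a soil CRM mercury certification: a homogeneity
#' study of 12 bottles measured 4 times each, a collaborative study of 16
#' expert laboratories with 5 replicates, one laboratory with a deviating
#' mean (`L4`) and one with a deviating variance (`L14`), a stable classical
#' stability series, and a quarterly monitoring series.  The grand mean is
#' 4 mg/kg.  All values are synthetic.
#'
#' @param s_bb_rel true between-bottle SD in percent (default 1.2).
#' @param mean_shift shift of the mean-outlier lab in between-lab SDs
#'   (default 8).
#' @param sd_inflation within-lab SD inflation of the variance-outlier lab
#'   (default 8).
#' @return a `fixture_spec`.
#' @export
fixture_spec_soil_hg <- function(s_bb_rel = 1.2, mean_shift = 8,
                                 sd_inflation = 8) {
  fixture_spec(
    analytes = tibble(name = "Hg", unit = "mg/kg", mean = 4.0),
    homogeneity = list(n_bottles = 12, n_reps = 4, s_bb_rel = s_bb_rel,
                       s_wb_rel = 2.0),
    certification = list(n_labs = 16, n_reps = 5, sigma_lab_rel = 5.5,
                         sigma_rep_rel = 2.0,
                         outlier_mean = c(L4 = mean_shift),
                         outlier_sd = c(L14 = sd_inflation)),
    stability = list(n_dates = 13, step_days = 30, slope_rel_per_month = 0,
                     noise_rel = 1.0, start_date = as.Date("2022-01-01")),
    lts = list(n_points = 12, step_months = 3, drift_per_month = 0.002,
               noise_abs = 0.04, uncertainty_value = 0.17,
               uncertainty_definition = "2s",
               certification_date = as.Date("2023-01-01"))
  )
}

#' Canned fixture: two-element study with graded outlier pair (synthetic)
#'
#' Emulates a collaborative study of two elements (Ca, Mg) across 15
#' laboratories in which each element carries two extreme laboratories of
#' different severity: the most extreme laboratory masks the second, which
#' becomes statistically significant only after the first has been excluded.
#'
#' @param shift_major,shift_minor shifts of the two planted laboratories in
#'   between-lab SDs (defaults 12 and -7).
#' @return a `fixture_spec`.
#' @export
fixture_spec_two_element <- function(shift_major = 12, shift_minor = -7) {
  fixture_spec(
    analytes = tibble(name = c("Ca", "Mg"), unit = "mg/kg",
                      mean = c(1200, 150)),
    certification = list(n_labs = 15, n_reps = 4, sigma_lab_rel = 3.0,
                         sigma_rep_rel = 1.5,
                         outlier_mean = c(L2 = shift_major, L9 = shift_minor),
                         outlier_sd = numeric(0))
  )
}

#' Canned fixture: accelerated stability study (synthetic)
#'
#' Emulates an Arrhenius stability study: reference samples stored at -80
#' degC (assumed inert) and four stressed temperature levels measured at
#' five time points, with first-order degradation following the Arrhenius
#' law with activation energy 80 kJ/mol.
#'
#' @param Ea_kJ_mol true activation energy (default 80).
#' @param noise_ln_sd measurement noise on the log scale (default 0.01).
#' @return a `fixture_spec`.
#' @export
fixture_spec_arrhenius <- function(Ea_kJ_mol = 80, noise_ln_sd = 0.01) {
  fixture_spec(
    analytes = tibble(name = "compound_A", unit = "mg/kg", mean = 100),
    arrhenius = list(reference_temperature = -80,
                     temperatures = c(10, 25, 40, 55),
                     time_points = c(0.5, 1, 2, 4, 6),
                     n_rep = 2, Ea_kJ_mol = Ea_kJ_mol,
                     k_ref_per_month = 0.02, T_ref = 25,
                     noise_ln_sd = noise_ln_sd, n_reference = 6,
                     start_date = as.Date("2022-01-01"))
  )
}

arrhenius_rate <- function(T_c, Ea_J_mol, k_ref, T_ref_c) {
  k_ref * exp(-Ea_J_mol / .R_GAS * (1 / (T_c + 273.15) - 1 / (T_ref_c + 273.15)))
}

format_num <- function(x) {
  vapply(x, function(v) format(v, digits = 15, scientific = FALSE, trim = TRUE), "")
}

write_fixture_table <- function(df, path, meta = NULL, format = "csv") {
  if (format == "xlsx") {
    sheets <- list(Data = df)
    if (!is.null(meta)) {
      sheets$Meta <- data.frame(key = names(meta),
                                value = unname(vapply(meta, as.character, "")))
    }
    write_xlsx_template(sheets, path)
  } else {
    num <- vapply(df, is.numeric, TRUE)
    out <- df
    for (nm in names(out)[num]) out[[nm]] <- format_num(out[[nm]])
    for (nm in names(out)) if (inherits(df[[nm]], "Date")) {
      out[[nm]] <- format(df[[nm]], "%Y-%m-%d")
    }
    lines <- c(
      if (!is.null(meta)) sprintf("# %s: %s", names(meta),
                                  vapply(meta, as.character, "")),
      paste(names(out), collapse = ","),
      do.call(paste, c(unname(as.list(out)), sep = ","))
    )
    readr::write_lines(lines, path)
  }
  path
}

#' Generate synthetic fixture files with known ground truth
#'
#' Draws one realization of the campaign defined by a [fixture_spec()] and
#' writes all applicable template files (homogeneity, classical stability,
#' accelerated stability, one certification file per laboratory, monitoring)
#' plus a machine-readable `truth.json` describing the generating
#' parameters.  Output is deterministic for a fixed seed and specification.
#'
#' @param spec a `fixture_spec`.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param format `"csv"` (default) or `"xlsx"`.
#' @return a list with `paths` (named list of generated files) and `truth`
#'   (the ground-truth record).
#' @export
make_fixture <- function(spec, seed, dir = tempfile("fixture"),
                         format = c("csv", "xlsx")) {
  stopifnot(inherits(spec, "fixture_spec"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- format
  paths <- list()
  truth <- list(seed = seed,
                analytes = as.data.frame(spec$analytes))

  withr::with_seed(seed, {
    # --- homogeneity ------------------------------------------------------
    if (!is.null(spec$homogeneity)) {
      h <- spec$homogeneity
      rows <- purrr::map_dfr(seq_len(nrow(spec$analytes)), function(ai) {
        a <- spec$analytes[ai, ]
        bottle_means <- a$mean * (1 + rnorm(h$n_bottles, 0, h$s_bb_rel / 100))
        purrr::map_dfr(seq_len(h$n_bottles), function(b) {
          tibble(analyte = a$name, unit = a$unit,
                 bottle = sprintf("B%02d", b),
                 replicate = seq_len(h$n_reps),
                 value = bottle_means[b] +
                   a$mean * rnorm(h$n_reps, 0, h$s_wb_rel / 100))
        })
      })
      paths$homogeneity <- write_fixture_table(
        rows, file.path(dir, paste0("homogeneity.", ext)), format = format)
      truth$homogeneity <- h
    }

    # --- certification ----------------------------------------------------
    if (!is.null(spec$certification)) {
      cc <- spec$certification
      labs <- sprintf("L%d", seq_len(cc$n_labs))
      lab_paths <- list()
      lab_truth <- list()
      for (lab in labs) {
        tabs <- purrr::map_dfr(seq_len(nrow(spec$analytes)), function(ai) {
          a <- spec$analytes[ai, ]
          sigma_lab <- a$mean * cc$sigma_lab_rel / 100
          shift <- (cc$outlier_mean[lab] %||% 0)
          shift <- if (is.na(shift)) 0 else shift
          infl <- (cc$outlier_sd[lab] %||% 1)
          infl <- if (is.na(infl)) 1 else infl
          # planted mean-outlier labs carry their bias exactly (the shift is
          # the ground truth); unremarkable labs draw a random lab effect
          lab_mean <- a$mean + sigma_lab * (if (shift != 0) shift else rnorm(1))
          tibble(analyte = a$name, unit = a$unit,
                 replicate = seq_len(cc$n_reps),
                 value = lab_mean +
                   a$mean * cc$sigma_rep_rel / 100 * infl * rnorm(cc$n_reps))
        })
        p <- write_fixture_table(
          tabs, file.path(dir, sprintf("certification_%s.%s", lab, ext)),
          meta = list(Lab = lab), format = format)
        lab_paths[[lab]] <- p
      }
      paths$certification <- unlist(lab_paths)
      truth$certification <- cc[setdiff(names(cc), c("outlier_mean", "outlier_sd"))]
      truth$certification$outlier_mean <- as.list(cc$outlier_mean)
      truth$certification$outlier_sd <- as.list(cc$outlier_sd)
    }

    # --- classical stability ---------------------------------------------
    if (!is.null(spec$stability)) {
      st <- spec$stability
      dates <- st$start_date + (seq_len(st$n_dates) - 1) * st$step_days
      months <- months_elapsed(dates)
      rows <- purrr::map_dfr(seq_len(nrow(spec$analytes)), function(ai) {
        a <- spec$analytes[ai, ]
        tibble(analyte = a$name, unit = a$unit, date = dates,
               value = a$mean * (1 + st$slope_rel_per_month / 100 * months) +
                 a$mean * rnorm(length(dates), 0, st$noise_rel / 100))
      })
      paths$stability <- write_fixture_table(
        rows, file.path(dir, paste0("stability.", ext)), format = format)
      truth$stability <- st
    }

    # --- accelerated (Arrhenius) stability -------------------------------
    if (!is.null(spec$arrhenius)) {
      ar <- spec$arrhenius
      a <- spec$analytes[1, ]
      k_true <- arrhenius_rate(ar$temperatures, ar$Ea_kJ_mol * 1000,
                               ar$k_ref_per_month, ar$T_ref)
      ref <- tibble(analyte = a$name, unit = a$unit, date = ar$start_date,
                    temperature = ar$reference_temperature,
                    value = a$mean * exp(rnorm(ar$n_reference, 0, ar$noise_ln_sd)))
      stressed <- purrr::map_dfr(seq_along(ar$temperatures), function(ti) {
        purrr::map_dfr(ar$time_points, function(tm) {
          date <- ar$start_date + round(tm / 12 * 365.25)
          tibble(analyte = a$name, unit = a$unit, date = date,
                 temperature = ar$temperatures[ti],
                 value = a$mean * exp(-k_true[ti] * tm +
                                        rnorm(ar$n_rep, 0, ar$noise_ln_sd)))
        })
      })
      paths$arrhenius <- write_fixture_table(
        bind_rows(ref, stressed),
        file.path(dir, paste0("stability_arrhenius.", ext)), format = format)
      truth$arrhenius <- c(ar[setdiff(names(ar), "start_date")],
                           list(start_date = format(ar$start_date, "%Y-%m-%d"),
                                k_true = as.list(setNames(k_true,
                                  paste0("T", ar$temperatures)))))
    }

    # --- long-term stability monitoring ----------------------------------
    if (!is.null(spec$lts)) {
      lt <- spec$lts
      a <- spec$analytes[1, ]
      months <- seq_len(lt$n_points) * lt$step_months
      dates <- lt$certification_date + round(months / 12 * 365.25)
      values <- a$mean + lt$drift_per_month * months +
        rnorm(lt$n_points, 0, lt$noise_abs)
      df <- tibble(date = dates, value = values,
                   comment = ifelse(seq_len(lt$n_points) == 3,
                                    "instrument recalibrated", NA))
      paths$lts <- write_fixture_table(
        df, file.path(dir, paste0("lts.", ext)),
        meta = list(analyte = a$name, unit = a$unit,
                    certified_value = a$mean,
                    uncertainty_value = lt$uncertainty_value,
                    uncertainty_definition = lt$uncertainty_definition,
                    certification_date = format(lt$certification_date, "%Y-%m-%d")),
        format = format)
      truth$lts <- c(lt[setdiff(names(lt), "certification_date")],
                     list(certification_date = format(lt$certification_date,
                                                      "%Y-%m-%d")))
    }
  })

  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  paths$truth <- truth_path
  list(paths = paths, truth = truth, dir = dir)
}
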