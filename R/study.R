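#' Configuration of a synthetic two-protocol agreement study
#'
#' Defines the simulated cohort: number of subjects, between-subject
#' variation of organ kinetics around the default targets, lesion burden,
#' image noise, blood glucose distribution (truncated below the clinical
#' exclusion bound of 11 mmol/L, i.e. 198 mg/dl) and the gap-model family
#' used for the two-short-dynamic arm. All randomness flows from `seed`.
#'
#' @param n_subjects number of subjects (default 21).
#' @param seed master seed.
#' @param sigma0 image noise scale, kBq/ml at 1 kBq/ml and a 1-min frame.
#' @param glucose_mean,glucose_sd,glucose_min,glucose_max blood glucose
#'   distribution, mmol/L (truncated normal).
#' @param organ_cv between-subject coefficient of variation applied to each
#'   organ's MR and DV targets.
#' @param n_lesions_range inclusive range of the per-subject lesion count.
#' @param lesion_mr_range,lesion_dv_range uniform sampling ranges for
#'   lesion targets (µmol/min/ml; percent).
#' @param gap_family family passed to [fit_gap_model()].
#' @param dose_MBq,weight_kg injected activity and body weight used for the
#'   SUV maps.
#' @param organ_sphere_mm,liver_sphere_mm fixed VOI diameters for normal
#'   organs and for the liver.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_subjects = 21, seed = 1L, sigma0 = 0.4,
                         glucose_mean = 5.5, glucose_sd = 1.0,
                         glucose_min = 3.5, glucose_max = 11,
                         organ_cv = 0.25, n_lesions_range = c(1, 3),
                         lesion_mr_range = c(0.05, 0.25),
                         lesion_dv_range = c(20, 60),
                         gap_family = "tri_exponential",
                         dose_MBq = 260, weight_kg = 70,
                         organ_sphere_mm = 10, liver_sphere_mm = 25) {
  stopifnot(n_subjects >= 1, sigma0 >= 0, glucose_max <= 11,
            glucose_min < glucose_max, organ_cv >= 0,
            n_lesions_range[1] >= 0, n_lesions_range[2] <= 6)
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              sigma0 = sigma0, glucose_mean = glucose_mean,
              glucose_sd = glucose_sd, glucose_min = glucose_min,
              glucose_max = glucose_max, organ_cv = organ_cv,
              n_lesions_range = as.integer(n_lesions_range),
              lesion_mr_range = lesion_mr_range,
              lesion_dv_range = lesion_dv_range,
              gap_family = gap_family, dose_MBq = dose_MBq,
              weight_kg = weight_kg, organ_sphere_mm = organ_sphere_mm,
              liver_sphere_mm = liver_sphere_mm)
  class(cfg) <- "study_config"
  cfg
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v > lo && v < hi) break
    }
    out[i] <- v
  }
  out
}

# per-subject draw of phantom spec + glucose + input function
draw_subject <- function(cfg, subject_seed) {
  set.seed(subject_seed)
  glucose <- rtrunc_norm(1, cfg$glucose_mean, cfg$glucose_sd,
                         cfg$glucose_min, cfg$glucose_max)
  base <- organ_kinetic_defaults(glucose = glucose)
  organs <- base[base$organ != "lesion", ]
  for (i in seq_len(nrow(organs))) {
    mr <- rtrunc_norm(1, organs$mr_fdg[i], cfg$organ_cv * organs$mr_fdg[i],
                      organs$mr_fdg[i] * 0.3, organs$mr_fdg[i] * 3)
    dv <- rtrunc_norm(1, organs$dv_percent[i], cfg$organ_cv * organs$dv_percent[i],
                      organs$dv_percent[i] * 0.3, min(organs$dv_percent[i] * 3, 95))
    organs$mr_fdg[i] <- mr
    organs$dv_percent[i] <- dv
  }
  tbl <- rbind(organs, base[base$organ == "lesion", ])
  tbl$ki <- tbl$mr_fdg / glucose
  v <- tbl$dv_percent / 100
  tbl$vb <- 0.25 * v
  beta <- 0.35
  tbl$K1 <- tbl$ki + (v - tbl$vb) * beta
  tbl$k3 <- tbl$ki * beta / tbl$K1
  tbl$k2 <- beta - tbl$k3

  n_les <- sample(seq(cfg$n_lesions_range[1], cfg$n_lesions_range[2]), 1)
  slots <- lesion_candidate_centers()
  centers <- slots[sample(length(slots), n_les)]
  lesions <- lapply(centers, function(ctr) {
    mr <- stats::runif(1, cfg$lesion_mr_range[1], cfg$lesion_mr_range[2])
    dv <- stats::runif(1, cfg$lesion_dv_range[1], cfg$lesion_dv_range[2])
    ki <- mr / glucose; vv <- dv / 100; vb <- 0.25 * vv
    K1 <- ki + (vv - vb) * beta
    k3 <- ki * beta / K1
    list(center_mm = ctr, diameter_mm = stats::runif(1, 12, 18),
         params = kinetic_params(K1, beta - k3, k3, vb))
  })
  amp_scale <- stats::runif(1, 0.8, 1.2)
  f <- input_function("feng4",
                      amplitudes = c(851.1, 21.88, 20.81) * amp_scale,
                      rates = c(4.1339, 0.01043, 0.1191),
                      t_peak_offset = stats::runif(1, 0.25, 0.55))
  spec <- default_phantom_spec(organ_table = tbl, lesions = lesions,
                               blood_glucose = glucose)
  list(spec = spec, f = f, glucose = glucose, organ_table = tbl,
       lesions = lesions)
}

voxel_center_of_mm <- function(center_mm, voxel_mm) {
  as.integer(round(center_mm / voxel_mm + 0.5))
}

# VOI set defined on the standard maps and copied unchanged to the
# two-short maps: fixed spheres for normal organs (anchored at the known
# region centers), 41% isocontour for lesions seeded at the lesion centers.
subject_vois <- function(subj, maps_std, cfg) {
  spec <- subj$spec
  shape <- spec$shape
  vm <- spec$voxel_mm
  vois <- list()
  for (nm in names(spec$regions)) {
    if (nm == "aorta") next
    geo <- spec$regions[[nm]]$geometry
    if (startsWith(nm, "lesion")) {
      seed_vox <- voxel_center_of_mm(geo$center_mm, vm)
      vois[[nm]] <- segment_threshold41(maps_std$mr, seed_vox)
    } else {
      ctr_mm <- if (geo$type == "sphere") geo$center_mm else (geo$lo_mm + geo$hi_mm) / 2
      dia <- if (nm == "liver") cfg$liver_sphere_mm else cfg$organ_sphere_mm
      vois[[nm]] <- sphere_voi(voxel_center_of_mm(ctr_mm, vm), dia, shape, vm)
    }
  }
  vois
}

#' Run the full two-protocol agreement study
#'
#' For each synthetic subject: render the standard 0–75 min acquisition,
#' take the two-short-dynamic dataset as the 0–6 + 60–75 min subset of the
#' same session, extract the aorta IDIF for both arms (the two-short IDIF
#' passes through the merged-TAC CSV dialect and the gap model), compute
#' MR_FDG / DV / SUV maps with the identical fit code for both arms, define
#' VOIs on the standard maps and copy them to the two-short maps, and
#' extract max/mean/peak per region. The pooled paired values then run
#' through the [agreement_battery()] per metric, for normal organs, lesions
#' and all regions pooled.
#'
#' @param cfg a [study_config()].
#' @param out_dir optional directory; when given, the configuration, the
#'   paired-sample table, the agreement reports, the per-subject merged
#'   IDIF CSVs and a run manifest are written there.
#' @param verbose print per-subject progress.
#' @return object of class `study_result`: `pairs` (long paired-sample
#'   table), `report_organs`, `report_lesions`, `report_pooled`,
#'   `summary_by_organ` (Table-2-style layout), `cfg`.
#' @export
run_study <- function(cfg, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  std <- build_schedule("standard")
  tss <- build_schedule("two_short")
  pairs <- list()
  suv_rows <- list()
  subject_seeds <- cfg$seed * 10007L + seq_len(cfg$n_subjects)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  skipped <- integer(0)
  for (i in seq_len(cfg$n_subjects)) {
    subject_rows <- try({
    subj <- draw_subject(cfg, subject_seeds[i])
    img_std <- render_phantom(subj$spec, subj$f, std,
                              noise_model(cfg$sigma0, subject_seeds[i]))
    img_tsd <- subset_frames(img_std, tss)
    aorta_idx <- which(img_std$labels == match("aorta", img_std$region_names))

    idif_std <- extract_idif(img_std, aorta_idx)
    idif_tsd_raw <- extract_idif(img_tsd, aorta_idx)
    halves <- split_tac(idif_tsd_raw, at = 6)
    merged <- merge_tacs(halves$early, halves$late)
    csv_path <- if (!is.null(out_dir)) {
      file.path(out_dir, sprintf("subject%02d_idif_merged.csv", i))
    } else {
      tempfile(fileext = ".csv")
    }
    write_tac_csv(merged, csv_path)
    idif_tsd <- read_tac_csv(csv_path)
    if (is.null(out_dir)) unlink(csv_path)
    gap <- fit_gap_model(idif_tsd, family = cfg$gap_family)

    maps_std <- make_maps(img_std, idif_std, g = NULL, glucose = subj$glucose,
                          dose_MBq = cfg$dose_MBq, weight_kg = cfg$weight_kg)
    maps_tsd <- make_maps(img_tsd, idif_tsd, g = gap, glucose = subj$glucose,
                          dose_MBq = cfg$dose_MBq, weight_kg = cfg$weight_kg)

    vois <- subject_vois(subj, maps_std, cfg)
    sub_pairs <- list()
    sub_suv <- list()
    for (nm in names(vois)) {
      grp <- if (startsWith(nm, "lesion")) "lesion" else "organ"
      for (mp in c("mr", "dv")) {
        st_std <- region_stats(maps_std[[mp]], vois[[nm]], subj$spec$voxel_mm)
        st_tsd <- region_stats(maps_tsd[[mp]], vois[[nm]], subj$spec$voxel_mm)
        if (!st_std$valid || !st_tsd$valid) next
        for (stat in c("max", "mean", "peak")) {
          sub_pairs[[length(sub_pairs) + 1]] <- data.frame(
            subject = i, region = nm, group = grp,
            metric = paste0(toupper(mp), "-", stat),
            std = st_std[[stat]], tsd = st_tsd[[stat]],
            stringsAsFactors = FALSE)
        }
      }
      st_suv <- region_stats(maps_std$suv, vois[[nm]], subj$spec$voxel_mm)
      sub_suv[[length(sub_suv) + 1]] <- data.frame(
        subject = i, region = nm, group = grp,
        suv_max = st_suv$max, suv_mean = st_suv$mean, suv_peak = st_suv$peak,
        stringsAsFactors = FALSE)
    }
    list(pairs = sub_pairs, suv = sub_suv)
    }, silent = TRUE)
    if (inherits(subject_rows, "try-error")) {
      skipped <- c(skipped, i)
      warning(sprintf("subject %d skipped: %s", i,
                      conditionMessage(attr(subject_rows, "condition"))))
      next
    }
    pairs <- c(pairs, subject_rows$pairs)
    suv_rows <- c(suv_rows, subject_rows$suv)
    if (verbose) message(sprintf("subject %d/%d done", i, cfg$n_subjects))
  }
  if (length(skipped) == cfg$n_subjects) stop("every subject failed; no results")
  pairs <- do.call(rbind, pairs)
  suv_tab <- do.call(rbind, suv_rows)

  report_for <- function(sub) {
    if (!nrow(sub)) return(NULL)
    agreement_battery(sub)
  }
  res <- list(
    pairs = pairs,
    report_organs = report_for(pairs[pairs$group == "organ", ]),
    report_lesions = report_for(pairs[pairs$group == "lesion", ]),
    report_pooled = report_for(pairs),
    summary_by_organ = summarize_by_organ(pairs, suv_tab),
    suv = suv_tab,
    skipped = skipped,
    cfg = cfg)
  class(res) <- "study_result"
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(pairs, file.path(out_dir, "paired_samples.csv"),
                     row.names = FALSE)
    for (nm in c("report_organs", "report_lesions", "report_pooled")) {
      if (!is.null(res[[nm]])) {
        utils::write.csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    utils::write.csv(res$summary_by_organ,
                     file.path(out_dir, "summary_by_organ.csv"), row.names = FALSE)
    manifest <- list(package = "dynpatlak",
                     n_subjects = cfg$n_subjects, seed = cfg$seed,
                     files = list.files(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

# organ x metric x method summary (mean +/- sd across subjects)
summarize_by_organ <- function(pairs, suv_tab) {
  rows <- list()
  for (rg in unique(pairs$region)) {
    for (mt in unique(pairs$metric)) {
      d <- pairs[pairs$region == rg & pairs$metric == mt, ]
      if (!nrow(d)) next
      rows[[length(rows) + 1]] <- data.frame(
        region = rg, metric = mt,
        std_mean = mean(d$std), std_sd = stats::sd(d$std),
        tsd_mean = mean(d$tsd), tsd_sd = stats::sd(d$tsd),
        n = nrow(d), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(suv_tab)) {
    for (rg in unique(suv_tab$region)) {
      d <- suv_tab[suv_tab$region == rg, ]
      for (stat in c("max", "mean", "peak")) {
        v <- d[[paste0("suv_", stat)]]
        out <- rbind(out, data.frame(
          region = rg, metric = paste0("SUV-", stat),
          std_mean = mean(v), std_sd = stats::sd(v),
          tsd_mean = NA_real_, tsd_sd = NA_real_, n = nrow(d),
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>", x$cfg$n_subjects, "subjects,",
      length(unique(x$pairs$region)), "region labels,",
      nrow(x$pairs), "paired values\n")
  if (!is.null(x$report_pooled)) {
    cat("\nPooled agreement (std vs two-short):\n")
    print(format_report(x$report_pooled))
  }
  invisible(x)
}

format_report <- function(rep) {
  data.frame(
    metric = rep$metric,
    `A (CI)` = sprintf("%.3f (%.3f-%.3f)", rep$intercept_A, rep$intercept_lo, rep$intercept_hi),
    `B (CI)` = sprintf("%.3f (%.3f-%.3f)", rep$slope_B, rep$slope_lo, rep$slope_hi),
    `cusum p` = sprintf("%.2f", rep$cusum_p),
    bias = sprintf("%.4g", rep$ba_bias),
    LoA = sprintf("(%.4g, %.4g)", rep$ba_lower, rep$ba_upper),
    rho = sprintf("%.3f (%.3f-%.3f)", rep$spearman_rho, rep$spearman_lo, rep$spearman_hi),
    check.names = FALSE)
}

#' Human-readable summary of a persisted study run
#'
#' Reads the artifacts written by [run_study()] into a printable summary,
#' and optionally renders Passing–Bablok / Bland–Altman figures per metric.
#'
#' @param run_dir directory written by `run_study(cfg, out_dir =)`.
#' @param figures if `TRUE`, write `<metric>_pb.png` / `<metric>_ba.png`
#'   into `run_dir`.
#' @return list of the loaded tables, invisibly; prints the formatted
#'   agreement report.
#' @export
study_report <- function(run_dir, figures = FALSE) {
  needed <- c("config.json", "paired_samples.csv", "report_pooled.csv",
              "summary_by_organ.csv", "manifest.json")
  missing <- needed[!file.exists(file.path(run_dir, needed))]
  if (length(missing)) {
    stop("run directory is incomplete; missing: ", paste(missing, collapse = ", "))
  }
  cfg <- jsonlite::read_json(file.path(run_dir, "config.json"), simplifyVector = TRUE)
  pairs <- utils::read.csv(file.path(run_dir, "paired_samples.csv"))
  pooled <- utils::read.csv(file.path(run_dir, "report_pooled.csv"))
  summ <- utils::read.csv(file.path(run_dir, "summary_by_organ.csv"))
  cat(sprintf("Study run: %d subjects, seed %d, gap family %s\n\n",
              cfg$n_subjects, cfg$seed, cfg$gap_family))
  print(format_report(pooled))
  if (figures) {
    for (mt in unique(pairs$metric)) {
      d <- pairs[pairs$metric == mt, ]
      fit <- passing_bablok(d$std, d$tsd)
      ba <- bland_altman(d$std, d$tsd)
      safe <- gsub("[^A-Za-z0-9]", "_", mt)
      grDevices::png(file.path(run_dir, paste0(safe, "_pb.png")), 600, 600)
      plot_passing_bablok(d$std, d$tsd, fit, main = mt)
      grDevices::dev.off()
      grDevices::png(file.path(run_dir, paste0(safe, "_ba.png")), 600, 600)
      plot_bland_altman(d$std, d$tsd, ba, main = mt)
      grDevices::dev.off()
    }
  }
  invisible(list(cfg = cfg, pairs = pairs, report_pooled = pooled,
                 summary_by_organ = summ))
}
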