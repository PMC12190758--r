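# End-to-end orchestration: simulate a cohort, forward-simulate raw data
# per tumor, run every reconstruction/fitting stage, reduce to ROI
# biomarkers, and join the measured metrics to the ground-truth table.

#' Pipeline run configuration
#'
#' A fully serialisable record of everything a run depends on; re-running
#' from the same configuration reproduces identical outputs.
#'
#' @param seed Master integer seed.
#' @param cohort A [cohort_config()].
#' @param shape Phantom grid per tumor.
#' @param epr_acq,dce_acq,dwi_acq,csi_acq Acquisition protocols (EPR
#'   reconstruction uses matched-grid settings by default for
#'   quantitative maps; see the methods vignette).
#' @param calib An [oximetry_calibration()].
#' @param aif An [aif_model()].
#' @param snr Named list of per-modality SNRs (`epr` is a scale on the
#'   average-derived noise; `dce`, `dwi`, `csi` are image/spectral SNRs).
#' @param modalities Character subset of
#'   `c("epr", "dce", "dwi", "csi")` to run.
#' @param out Output directory (`NULL` = no artifacts written).
#' @param resume If `TRUE`, per-tumor stages whose artifact files already
#'   exist are not recomputed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 7, cohort = cohort_config(seed = seed),
                            shape = c(16, 16, 16),
                            epr_acq = epr_acquisition(zerofill = 19,
                                                      tukey_r = 0),
                            dce_acq = dce_acquisition(),
                            dwi_acq = dwi_acquisition(),
                            csi_acq = csi_acquisition(),
                            calib = oximetry_calibration(),
                            aif = aif_model(),
                            snr = list(epr = 1, dce = 50, dwi = 50,
                                       csi = 100),
                            modalities = c("epr", "dce", "dwi", "csi"),
                            out = NULL, resume = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full simulation-and-analysis pipeline
#'
#' For every tumor in the cohort: build the phantom realising its
#' ground-truth row, forward-simulate each requested modality's raw
#' acquisition, run the corresponding reconstruction and fitting chain
#' (EPR: simulate -> reconstruct -> R2* fit -> pO2, HF10, median pO2;
#' DCE: RARE T1 fit -> SPGR inversion -> AUC1min/AUC10min; DWI: ADC fit;
#' CSI: peak quantification -> lactate/pyruvate ratio), reduce to ROI
#' biomarkers with [summarize_roi()], and join the measured columns onto
#' the cohort table. When `config$out` is set, per-tumor maps are written
#' as NIfTI volumes, the joined table as CSV, and a manifest JSON with
#' file hashes, seed and package version.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_run`: the measured `cohort` table, a
#'   `manifest` list, and the output directory (if any).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  tab <- simulate_cohort(config$cohort, aif = config$aif)
  outdir <- config$out
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)
  files <- character(0)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    tumor_id <- paste(row$mouse_id, row$tumor_site, sep = "_")
    tseed <- derive_seed(config$seed, 100 + i)
    res <- tryCatch(
      analyze_tumor(row, config, tseed),
      error = function(e) stop("stage failure for tumor ", tumor_id, ": ",
                               conditionMessage(e)))
    for (nm in c("median_po2", "hf10", "auc1", "auc10", "adc", "lac_pyr")) {
      tab[[nm]][i] <- res$summary[[nm]]
    }
    if (!is.null(outdir)) {
      write_tumor_maps <- function() {
        wrote <- character(0)
        if (!is.null(res$maps$po2)) {
          f <- file.path(outdir, paste0(tumor_id, "_po2.nii"))
          if (!(config$resume && file.exists(f))) {
            write_volume(res$maps$po2$po2, f,
                         sidecar = list(calib = unclass(config$calib)))
          }
          wrote <- c(wrote, f)
        }
        for (nm in c("auc1", "auc10")) {
          if (!is.null(res$maps[[nm]])) {
            f <- file.path(outdir, paste0(tumor_id, "_", nm, ".nii"))
            if (!(config$resume && file.exists(f))) {
              write_volume(res$maps[[nm]], f)
            }
            wrote <- c(wrote, f)
          }
        }
        if (!is.null(res$maps$adc)) {
          f <- file.path(outdir, paste0(tumor_id, "_adc.nii"))
          if (!(config$resume && file.exists(f))) {
            write_volume(res$maps$adc$adc, f)
          }
          wrote <- c(wrote, f)
        }
        wrote
      }
      files <- c(files, write_tumor_maps())
    }
  }
  manifest <- list(seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("qmriphantom")),
                   n_mice = length(unique(tab$mouse_id)),
                   n_tumors = nrow(tab),
                   modalities = config$modalities)
  if (!is.null(outdir)) {
    csv <- file.path(outdir, "cohort_measured.csv")
    utils::write.csv(tab, csv, row.names = FALSE)
    files <- c(files, csv)
    manifest$files <- lapply(sort(files), function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(cohort = tab, manifest = manifest, out = outdir),
            class = "pipeline_run")
}

# One tumor through every requested modality chain.
analyze_tumor <- function(row, config, seed) {
  phantom <- phantom_for_row(row, config$shape)
  mask <- phantom$tumor_mask
  maps <- list()
  if ("epr" %in% config$modalities) {
    ks <- simulate_spi(phantom, config$epr_acq, config$calib, seed = seed,
                       snr_scale = config$snr$epr)
    imgs <- reconstruct_spi(ks, config$epr_acq)
    emask <- embed_mask(mask, imgs$grid, ks$offset, ks$grid)
    r2map <- fit_r2star(imgs, mask = emask)
    maps$po2 <- r2star_to_po2(r2map, config$calib)
    maps$po2_mask <- emask
  }
  if ("dce" %in% config$modalities) {
    dce <- simulate_dce(phantom, config$dce_acq, config$aif,
                        snr = config$snr$dce, seed = seed)
    t1map <- fit_t1(dce$rare, config$dce_acq$rare_trs,
                    mask = phantom$body_mask)
    conc <- signal_to_concentration(dce, t1map, config$dce_acq)
    aucs <- auc_metrics(conc, config$dce_acq)
    maps$auc1 <- aucs$auc1
    maps$auc10 <- aucs$auc10
  }
  if ("dwi" %in% config$modalities) {
    dwi <- simulate_dwi(phantom, config$dwi_acq, snr = config$snr$dwi,
                        seed = seed)
    maps$adc <- fit_adc(dwi, mask = phantom$body_mask)
  }
  if ("csi" %in% config$modalities) {
    csi <- simulate_csi(phantom, config$csi_acq, snr = config$snr$csi,
                        seed = seed)
    maps$lac_pyr <- quantify_peaks(csi)
  }
  # the pO2 map lives on the (possibly larger) recon grid, the other maps
  # on the phantom grid; reduce each on its own grid and merge
  summary <- summarize_roi(
    maps[intersect(names(maps), c("auc1", "auc10", "adc", "lac_pyr"))],
    mask = mask)
  if (!is.null(maps$po2)) {
    s_po2 <- summarize_roi(list(po2 = maps$po2), mask = maps$po2_mask)
    summary$median_po2 <- s_po2$median_po2
    summary$hf10 <- s_po2$hf10
  }
  list(summary = summary, maps = maps)
}

# Map a phantom-grid mask into the reconstruction grid (nearest-neighbour
# on voxel centres through the acquisition embedding).
embed_mask <- function(mask, recon_grid, offset, acq_grid) {
  d <- dim(mask)
  acq_mask <- array(FALSE, acq_grid)
  acq_mask[offset[1] + seq_len(d[1]), offset[2] + seq_len(d[2]),
           offset[3] + seq_len(d[3])] <- mask
  if (all(recon_grid == acq_grid)) return(acq_mask)
  idx <- lapply(1:3, function(i) {
    src <- round((seq_len(recon_grid[i]) - (floor(recon_grid[i] / 2) + 1)) *
                   acq_grid[i] / recon_grid[i]) + floor(acq_grid[i] / 2) + 1
    pmin(pmax(src, 1), acq_grid[i])
  })
  out <- acq_mask[idx[[1]], idx[[2]], idx[[3]]]
  dim(out) <- recon_grid
  out
}
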