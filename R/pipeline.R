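#' Load a co-registered NIfTI volume stack with acquisition metadata
#'
#' Reads the volumes, refuses mismatched geometry (grid or voxel size), and
#' attaches one acquisition record per volume.  The metadata may be a data
#' frame or the path of a JSON sidecar holding an array of per-volume
#' records with fields `mt_flip_deg`, `mt_offset_hz`, `mt_duration_s`,
#' `mt_bandwidth_hz`, `tr_s`, `te_s`, `read_flip_deg`, `role`.
#'
#' @param paths character vector of NIfTI file paths (3-D volumes), or a
#'   single 4-D volume path.
#' @param metadata per-volume acquisition table or JSON path.
#' @return a `volume_stack`.
#' @export
load_stack <- function(paths, metadata) {
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- as.data.frame(jsonlite::fromJSON(metadata))
  need <- c("mt_flip_deg", "mt_offset_hz", "mt_duration_s", "mt_bandwidth_hz",
            "tr_s", "te_s", "read_flip_deg", "role")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop("metadata is missing required fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  vols <- lapply(paths, RNifti::readNifti)
  if (length(vols) == 1L && length(dim(vols[[1]])) == 4L) {
    arr <- as.array(vols[[1]])
  } else {
    dims <- lapply(vols, dim)
    pix <- lapply(vols, function(v) RNifti::pixdim(v))
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
      stop("geometry mismatch: volumes have different grids", call. = FALSE)
    if (length(unique(vapply(pix, paste, "", collapse = "x"))) != 1L)
      stop("geometry mismatch: volumes have different voxel sizes",
           call. = FALSE)
    arr <- array(0, dim = c(dims[[1]], length(vols)))
    for (v in seq_along(vols)) arr[, , , v] <- as.array(vols[[v]])
  }
  if (dim(arr)[4] != nrow(metadata))
    stop(sprintf("count mismatch: %d volumes but %d metadata records",
                 dim(arr)[4], nrow(metadata)), call. = FALSE)
  structure(list(data = arr, meta = as.data.frame(metadata),
                 protocol = "loaded", sigma = NA_real_),
            class = "volume_stack")
}

#' Write a volume stack to NIfTI files with a JSON metadata sidecar
#'
#' @param stack a `volume_stack`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param voxel_mm voxel dimensions recorded in the NIfTI header.
#' @return invisibly, the paths written (volumes, then the sidecar).
#' @export
write_stack <- function(stack, dir, prefix = stack$protocol,
                        voxel_mm = c(1.56, 1.56, 10)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nvol <- dim(stack$data)[4]
  paths <- character(nvol)
  for (v in seq_len(nvol)) {
    img <- RNifti::asNifti(stack$data[, , , v])
    RNifti::pixdim(img) <- voxel_mm
    paths[v] <- file.path(dir, sprintf("%s_%02d.nii", prefix, v))
    RNifti::writeNifti(img, paths[v])
  }
  sidecar <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(stack$meta, sidecar, dataframe = "rows", na = "null",
                       auto_unbox = FALSE, digits = NA)
  invisible(c(paths, sidecar))
}

#' Run the full synthetic-cohort analysis
#'
#' Orchestrates the stages in acquisition order: simulate the cohort
#' (B1/B0/T1 supporting maps plus the requested MT protocols), extract
#' ROI-level index values, and run the statistical comparison (normality
#' gate, ANOVA for T1, Mann-Whitney age comparisons with effect sizes,
#' Kruskal-Wallis regional comparisons, index-versus-T1 regressions).
#' Deterministic given the configuration seed; optionally writes the cohort
#' table, comparison tables and a provenance record to `outdir`.
#'
#' @param config a [cohort_config()].
#' @param methods indices to compute (see [compute_indices()]).
#' @param mode ROI analysis convention, `"roi_signal_mean"` or `"map_mean"`.
#' @param reference_muscle reference tissue for the MTR correction.
#' @param outdir optional output directory for CSV/JSON products.
#' @return a list of class `mt_report`: `table` (cohort table),
#'   `age_comparisons` (data frame), `regional` (list), `t1_anova`,
#'   `regressions` (data frame), `normality` (per-index gate), `config`.
#' @export
run_all <- function(config,
                    methods = c("t1", "f_so", "mtsat", "mtr", "mtr_corr"),
                    mode = "roi_signal_mean", reference_muscle = "TP",
                    outdir = NULL) {
  if (!inherits(config, "cohort_config"))
    stop("'config' must come from cohort_config()", call. = FALSE)
  protocols <- c("b1", "b0", "vfa",
                 if (any(c("f_so", "mtr", "mtr_corr") %in% methods)) "singleoffset",
                 if ("mtsat" %in% methods) "mtsat",
                 if (any(c("f_ram", "f_yar") %in% methods)) "multioffset")
  cohort <- simulate_cohort(config, protocols)
  tab <- cohort_table(cohort, methods = methods, mode = mode,
                      reference_muscle = reference_muscle)
  mt_idx <- setdiff(unique(tab$index), "t1")
  normality <- vapply(unique(tab$index), function(ix)
    normality_gate(tab$value[tab$index == ix & is.finite(tab$value)]),
    character(1))
  age <- do.call(rbind, lapply(mt_idx, function(ix)
    as.data.frame(compare_age_groups(tab, ix))))
  regional <- lapply(mt_idx, function(ix) compare_regions(tab, ix))
  names(regional) <- mt_idx
  t1_res <- if ("t1" %in% tab$index) anova_t1(tab) else NULL
  regressions <- do.call(rbind, lapply(mt_idx, function(ix) {
    r <- correlate_with_t1(tab, ix)
    data.frame(index = ix, pearson_r = r$pearson_r, p = r$p,
               slope = r$slope, intercept = r$intercept, n = r$n)
  }))
  report <- structure(list(table = tab, age_comparisons = age,
                           regional = regional, t1_anova = t1_res,
                           regressions = regressions, normality = normality,
                           config = config),
                      class = "mt_report")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.csv(tab, file.path(outdir, "cohort_table.csv"), row.names = FALSE)
    write.csv(age, file.path(outdir, "age_comparisons.csv"), row.names = FALSE)
    write.csv(regressions, file.path(outdir, "t1_regressions.csv"),
              row.names = FALSE)
    prov <- list(package = "mtcalf",
                 version = as.character(packageVersion("mtcalf")),
                 seed = config$seed, methods = methods, mode = mode,
                 n_young = config$n_young, n_senior = config$n_senior,
                 snr = config$snr, grid = config$grid)
    jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.mt_report <- function(x, ...) {
  cat(sprintf("MT cohort report: %d young / %d senior subjects, indices: %s\n",
              x$config$n_young, x$config$n_senior,
              paste(unique(x$table$index), collapse = ", ")))
  cat("\nAge comparisons (Mann-Whitney, pooled muscles):\n")
  print(x$age_comparisons, row.names = FALSE, digits = 3)
  if (!is.null(x$t1_anova))
    cat(sprintf("\nT1 two-way ANOVA: p(age) = %.3g, p(region) = %.3g, p(interaction) = %.3g\n",
                x$t1_anova$p_age, x$t1_anova$p_region,
                x$t1_anova$p_interaction))
  cat("\nIndex vs T1 regression:\n")
  print(x$regressions, row.names = FALSE, digits = 3)
  invisible(x)
}
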