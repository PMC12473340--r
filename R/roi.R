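#' ROI mean of a voxel map
#'
#' @param map 3-D array.
#' @param labels integer label array of the same shape.
#' @param label the label value to average over.
#' @return mean of `map` over the labelled voxels.
#' @export
roi_mean_map <- function(map, labels, label) {
  if (!all(dim(map) == dim(labels)))
    stop("geometry mismatch between map and labels", call. = FALSE)
  idx <- which(labels == label)
  if (!length(idx))
    stop(sprintf("missing ROI: label %s has no voxels", label), call. = FALSE)
  mean(map[idx])
}

# one 3-D volume of a stack, with singleton dimensions preserved
stack_volume <- function(stack, v) {
  d <- dim(stack$data)
  out <- stack$data[, , , v, drop = FALSE]
  dim(out) <- d[1:3]
  out
}

stack_roi_means <- function(stack, labels, label) {
  idx <- which(labels == label)
  if (!length(idx))
    stop(sprintf("missing ROI: label %s has no voxels", label), call. = FALSE)
  nvol <- dim(stack$data)[4]
  vapply(seq_len(nvol), function(v) mean(stack$data[, , , v][idx]), numeric(1))
}

check_labels_present <- function(labels, wanted) {
  present <- sort(unique(as.integer(labels[labels > 0])))
  miss <- setdiff(wanted, present)
  if (length(miss))
    stop("missing ROI labels in volume: ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

single_offset_pulse_from_meta <- function(meta) {
  i <- which(meta$role == "mt")[1]
  rf_pulse(meta$mt_flip_deg[i], meta$mt_offset_hz[i], meta$mt_duration_s[i],
           meta$mt_bandwidth_hz[i], meta$tr_s[i])
}

# voxelwise MTR and B1 error over one label (for the k-factor fit)
reference_mtr_voxels <- function(so_stack, b1_stack, labels, label) {
  idx <- which(labels == label)
  if (!length(idx))
    stop(sprintf("missing reference ROI: label %s", label), call. = FALSE)
  i_mt <- which(so_stack$meta$role == "mt")[1]
  i_ref <- which(so_stack$meta$role == "reference")[1]
  s_mt <- so_stack$data[, , , i_mt][idx]
  s_ref <- so_stack$data[, , , i_ref][idx]
  ok <- s_ref > 0
  list(mtr = 1 - s_mt[ok] / s_ref[ok],
       b1_rel = b1_stack$data[, , , 1][idx][ok])
}

#' Compute MT indices for the muscles of one subject
#'
#' Runs the estimation chain on simulated (or loaded) acquisition stacks.
#' In `"roi_signal_mean"` mode (the default analysis convention) signals are
#' first averaged over each muscle ROI and every index is computed once per
#' ROI from the mean signals; `"map_mean"` computes voxelwise index maps and
#' averages them afterwards.
#'
#' Indices: `t1` (VFA, seconds), `f_so` (single-offset qMT macromolecular
#' fraction), `mtsat` (B1-corrected, percent units), `mtr` and `mtr_corr`
#' (fractions; the correction uses a per-subject k-factor fitted on the
#' reference-tissue voxels), and optionally `f_ram` / `f_yar` (multi-offset
#' two-pool fits, requiring a `"multioffset"` stack).
#'
#' @param stacks named list of `volume_stack` objects (needs `singleoffset`,
#'   `mtsat`, `vfa`, `b1`, and optionally `b0` and `multioffset`).
#' @param labels integer ROI label array.
#' @param muscles character names of the ROIs, in label order (label `i` is
#'   `muscles[i]`).
#' @param reference_muscle reference tissue for the MTR k-factor fit
#'   (default `"TP"`, tibialis posterior; must be one of `muscles`).
#' @param mode `"roi_signal_mean"` or `"map_mean"`.
#' @param methods indices to compute.
#' @param use_b0 use the dual-echo stack to correct saturation offsets
#'   (default `TRUE` when a `b0` stack is present).
#' @return a data frame with columns `muscle`, `index`, `value`.
#' @export
compute_indices <- function(stacks, labels, muscles,
                            reference_muscle = "TP",
                            mode = c("roi_signal_mean", "map_mean"),
                            methods = c("t1", "f_so", "mtsat", "mtr",
                                        "mtr_corr"),
                            use_b0 = "b0" %in% names(stacks)) {
  mode <- match.arg(mode)
  methods <- match.arg(methods, c("t1", "f_so", "f_ram", "f_yar", "mtsat",
                                  "mtr", "mtr_corr"), several.ok = TRUE)
  check_labels_present(labels, seq_along(muscles))
  need <- c(vfa = any(c("t1", "f_so", "f_ram", "f_yar") %in% methods),
            singleoffset = any(c("f_so", "mtr", "mtr_corr") %in% methods),
            mtsat = "mtsat" %in% methods,
            multioffset = any(c("f_ram", "f_yar") %in% methods),
            b1 = TRUE)
  for (nm in names(need)[need])
    if (is.null(stacks[[nm]]))
      stop(sprintf("missing input: protocol stack '%s' is required for the requested methods", nm),
           call. = FALSE)

  b1_map <- stack_volume(stacks$b1, 1)
  b0_map <- if (use_b0 && !is.null(stacks$b0)) {
    m <- stacks$b0$meta
    b0_from_dual_echo(stack_volume(stacks$b0, 1), stack_volume(stacks$b0, 2),
                      m$te_s[1], m$te_s[2])
  } else array(0, dim(labels))

  k_fit <- NULL
  if ("mtr_corr" %in% methods) {
    ref_lab <- match(reference_muscle, muscles)
    if (is.na(ref_lab))
      stop("reference_muscle must be one of the labelled muscles", call. = FALSE)
    rv <- reference_mtr_voxels(stacks$singleoffset, stacks$b1, labels, ref_lab)
    k_fit <- fit_k(rv$mtr, rv$b1_rel - 1)
  }

  rows <- list()
  push <- function(muscle, index, value)
    rows[[length(rows) + 1L]] <<- data.frame(muscle = muscle, index = index,
                                             value = value)
  for (i in seq_along(muscles)) {
    mus <- muscles[i]
    if (mode == "roi_signal_mean") {
      vals <- roi_indices_from_means(stacks, labels, i, b1_map, b0_map,
                                     methods, k_fit)
    } else {
      vals <- roi_indices_map_mean(stacks, labels, i, b1_map, b0_map,
                                   methods, k_fit)
    }
    for (nm in names(vals)) push(mus, nm, vals[[nm]])
  }
  do.call(rbind, rows)
}

# index set from ROI-mean signals (one estimation per ROI)
roi_indices_from_means <- function(stacks, labels, label, b1_map, b0_map,
                                   methods, k_fit) {
  b1m <- roi_mean_map(b1_map, labels, label)
  b0m <- roi_mean_map(b0_map, labels, label)
  out <- list()
  ra <- NULL
  if (any(c("t1", "f_so", "f_ram", "f_yar") %in% methods)) {
    sv <- stack_roi_means(stacks$vfa, labels, label)
    mv <- stacks$vfa$meta
    t1fit <- vfa_fit_t1(sv, mv$read_flip_deg, mv$tr_s[1], b1m)
    ra <- 1 / t1fit$t1
    if ("t1" %in% methods) out$t1 <- t1fit$t1
  }
  if (any(c("f_so", "mtr", "mtr_corr") %in% methods)) {
    so <- stack_roi_means(stacks$singleoffset, labels, label)
    i_mt <- which(stacks$singleoffset$meta$role == "mt")[1]
    i_ref <- which(stacks$singleoffset$meta$role == "reference")[1]
    sn <- so[i_mt] / so[i_ref]
    if ("f_so" %in% methods) {
      p <- single_offset_pulse_from_meta(stacks$singleoffset$meta)
      out$f_so <- solve_single_offset(sn, p, ra, b1_rel = b1m, b0_hz = b0m)$f
    }
    if ("mtr" %in% methods) out$mtr <- compute_mtr(so[i_mt], so[i_ref])
    if ("mtr_corr" %in% methods)
      out$mtr_corr <- apply_mtr_correction(compute_mtr(so[i_mt], so[i_ref]),
                                           b1m - 1, k_fit)
  }
  if ("mtsat" %in% methods) {
    sm <- stack_roi_means(stacks$mtsat, labels, label)
    mv <- stacks$mtsat$meta
    out$mtsat <- compute_mtsat(sm[mv$role == "pdw"], sm[mv$role == "mt"],
                               sm[mv$role == "t1w"], mv$read_flip_deg,
                               mv$tr_s[1], b1m)
  }
  if (any(c("f_ram", "f_yar") %in% methods)) {
    mo <- stack_roi_means(stacks$multioffset, labels, label)
    meta <- stacks$multioffset$meta
    i_mt <- which(meta$role == "mt")
    i_ref <- which(meta$role == "reference")[1]
    sn <- mo[i_mt] / mo[i_ref]
    ptab <- meta[i_mt, ]
    for (mode_nm in intersect(c("f_ram", "f_yar"), methods)) {
      fit <- qmt_fit(sn, ptab, ra,
                     mode = if (mode_nm == "f_ram") "ramani" else "yarnykh",
                     b1_rel = b1m, b0_hz = b0m)
      out[[mode_nm]] <- fit$f
    }
  }
  out
}

# voxelwise maps averaged afterwards
roi_indices_map_mean <- function(stacks, labels, label, b1_map, b0_map,
                                 methods, k_fit) {
  idx <- which(labels == label)
  if (!length(idx))
    stop(sprintf("missing ROI: label %s has no voxels", label), call. = FALSE)
  b1v <- b1_map[idx]; b0v <- b0_map[idx]
  nv <- length(idx)
  out <- list()
  grab <- function(stack) {
    nvol <- dim(stack$data)[4]
    out <- matrix(0, nv, nvol)
    for (v in seq_len(nvol)) out[, v] <- stack$data[, , , v][idx]
    out
  }
  ra_v <- NULL
  if (any(c("t1", "f_so", "f_ram", "f_yar") %in% methods)) {
    sv <- grab(stacks$vfa); mv <- stacks$vfa$meta
    t1v <- vapply(seq_len(nv), function(j) {
      r <- try(vfa_fit_t1(sv[j, ], mv$read_flip_deg, mv$tr_s[1], b1v[j]),
               silent = TRUE)
      if (inherits(r, "try-error")) NA_real_ else r$t1
    }, numeric(1))
    ra_v <- 1 / t1v
    if ("t1" %in% methods) out$t1 <- mean(t1v, na.rm = TRUE)
  }
  if (any(c("f_so", "mtr", "mtr_corr") %in% methods)) {
    so <- grab(stacks$singleoffset)
    i_mt <- which(stacks$singleoffset$meta$role == "mt")[1]
    i_ref <- which(stacks$singleoffset$meta$role == "reference")[1]
    snv <- so[, i_mt] / so[, i_ref]
    if ("f_so" %in% methods) {
      p <- single_offset_pulse_from_meta(stacks$singleoffset$meta)
      fv <- vapply(seq_len(nv), function(j) {
        r <- try(suppressWarnings(
          solve_single_offset(min(max(snv[j], 1e-6), 1 - 1e-9), p, ra_v[j],
                              b1_rel = b1v[j], b0_hz = b0v[j])),
          silent = TRUE)
        if (inherits(r, "try-error")) NA_real_ else r$f
      }, numeric(1))
      out$f_so <- mean(fv, na.rm = TRUE)
    }
    mtrv <- 1 - snv
    if ("mtr" %in% methods) out$mtr <- mean(mtrv)
    if ("mtr_corr" %in% methods)
      out$mtr_corr <- mean(apply_mtr_correction(mtrv, b1v - 1, k_fit))
  }
  if ("mtsat" %in% methods) {
    sm <- grab(stacks$mtsat); mv <- stacks$mtsat$meta
    msv <- vapply(seq_len(nv), function(j) {
      r <- try(compute_mtsat(sm[j, mv$role == "pdw"], sm[j, mv$role == "mt"],
                             sm[j, mv$role == "t1w"], mv$read_flip_deg,
                             mv$tr_s[1], b1v[j]), silent = TRUE)
      if (inherits(r, "try-error")) NA_real_ else r
    }, numeric(1))
    out$mtsat <- mean(msv, na.rm = TRUE)
  }
  if (any(c("f_ram", "f_yar") %in% methods)) {
    mo <- grab(stacks$multioffset); meta <- stacks$multioffset$meta
    i_mt <- which(meta$role == "mt")
    i_ref <- which(meta$role == "reference")[1]
    ptab <- meta[i_mt, ]
    for (mode_nm in intersect(c("f_ram", "f_yar"), methods)) {
      fv <- vapply(seq_len(nv), function(j) {
        snj <- mo[j, i_mt] / mo[j, i_ref]
        r <- try(qmt_fit(pmin(snj, 1.5), ptab, ra_v[j],
                         mode = if (mode_nm == "f_ram") "ramani" else "yarnykh",
                         b1_rel = b1v[j], b0_hz = b0v[j]), silent = TRUE)
        if (inherits(r, "try-error") || !r$converged) NA_real_ else r$f
      }, numeric(1))
      out[[mode_nm]] <- mean(fv, na.rm = TRUE)
    }
  }
  out
}

#' Build the cohort table of per-subject, per-muscle index values
#'
#' Applies [compute_indices()] to every subject of a simulated (or loaded)
#' cohort and stacks the results into the long-format table consumed by the
#' statistics stage.
#'
#' @param cohort an `mt_cohort` from [simulate_cohort()].
#' @param ... passed to [compute_indices()] (`methods`, `mode`,
#'   `reference_muscle`, ...).
#' @return a data frame of class `cohort_table` with columns `subject`,
#'   `group`, `muscle`, `index`, `value`.
#' @export
cohort_table <- function(cohort, ...) {
  stopifnot(inherits(cohort, "mt_cohort"))
  rows <- lapply(cohort$subjects, function(s) {
    df <- compute_indices(s$stacks, s$phantom$labels, s$phantom$muscles, ...)
    cbind(data.frame(subject = s$id, group = s$group), df)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_table", "data.frame")
  out
}
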