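#' Per-voxel absolute percentage error map
#'
#' \eqn{APE_i = |x_i - x_{i,REF}| / |x_{i,REF}| \times 100\%}, evaluated on
#' labeled voxels only; unlabeled voxels are NA.  The reference value per
#' voxel comes from the label's entry in a truth table (mirroring contoured
#' regions with assigned reference values), or from a congruent reference
#' volume.
#'
#' @param pred Numeric array of predictions (or vector).
#' @param labels Integer array congruent with `pred` (0 = unlabeled).
#' @param truth Data frame with columns `label` and the reference column
#'   (`rho` or `rsp`), or NULL when `ref` is given.
#' @param target `"DENSITY"` or `"RSP"` — selects the truth column.
#' @param ref Optional reference volume congruent with `pred`, used instead
#'   of the truth table.
#' @return Array of APE values in percent, NA outside labels.
#' @export
ape_map <- function(pred, labels, truth = NULL, target = c("DENSITY", "RSP"),
                    ref = NULL) {
  target <- match.arg(target)
  stopifnot(length(pred) == length(labels))
  if (is.null(ref)) {
    if (is.null(truth)) stop("either a truth table or a reference volume is required")
    col <- if (target == "DENSITY") "rho" else "rsp"
    lut <- rep(NA_real_, max(c(truth$label, 1L)))
    lut[truth$label] <- truth[[col]]
    ref <- rep(NA_real_, length(pred))
    sel <- labels > 0
    ref[sel] <- lut[labels[sel]]
  } else {
    stopifnot(length(ref) == length(pred))
  }
  sel <- labels > 0 & !is.na(ref)
  zero <- sel & ref == 0
  if (any(zero)) {
    stop("zero reference value at evaluated voxel(s) of label(s): ",
         paste(sort(unique(labels[zero])), collapse = ", "))
  }
  out <- rep(NA_real_, length(pred))
  out[sel] <- abs(pred[sel] - ref[sel]) / abs(ref[sel]) * 100
  dim(out) <- dim(pred)
  out
}

#' Per-label MAPE rows
#'
#' Mean absolute percentage error per labeled region,
#' \eqn{MAPE = \frac{1}{N}\sum_i APE_i}, with the standard deviation of the
#' per-voxel APE (the "±" of the comparison tables) and the voxel count.
#' Labels with no voxels are omitted with a warning.
#'
#' @param ape APE array from [ape_map()] (percent).
#' @param labels Congruent integer label array.
#' @param model Model name recorded in the rows.
#' @param target `"DENSITY"` or `"RSP"` recorded in the rows.
#' @param tissue_names Optional named character vector label -> tissue name.
#' @param which_labels Labels to report (default: all present).
#' @return Data frame with columns `model`, `label`, `tissue`, `target`,
#'   `mape`, `ape_sd`, `n_voxels` (class `evaluation_report`).
#' @export
mape_by_label <- function(ape, labels, model = "model",
                          target = c("DENSITY", "RSP"),
                          tissue_names = NULL, which_labels = NULL) {
  target <- match.arg(target)
  stopifnot(length(ape) == length(labels))
  if (is.null(which_labels)) {
    which_labels <- setdiff(sort(unique(as.integer(labels))), 0L)
  }
  rows <- lapply(which_labels, function(lb) {
    v <- ape[labels == lb & !is.na(ape)]
    if (length(v) == 0) {
      warning("label ", lb, " has no evaluated voxels; row omitted")
      return(NULL)
    }
    data.frame(model = model, label = lb,
               tissue = if (!is.null(tissue_names) &&
                            !is.na(tissue_names[as.character(lb)]))
                 unname(tissue_names[as.character(lb)]) else as.character(lb),
               target = target, mape = mean(v),
               ape_sd = stats::sd(v), n_voxels = length(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(model = character(0), label = integer(0),
                      tissue = character(0), target = character(0),
                      mape = numeric(0), ape_sd = numeric(0),
                      n_voxels = integer(0))
  }
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' Compare per-tissue MAPE across models
#'
#' Builds the model-comparison table: one row per (tissue, target), one
#' column per model holding that model's MAPE, plus a `best` column naming
#' every model achieving the row minimum (ties flag all minima).  Cells a
#' model does not report (e.g. the DECT density model on normal lung) are NA
#' and never flagged.  All reports must cover the same (tissue, target)
#' pairs except for such documented omissions.
#'
#' @param reports List of `evaluation_report` data frames (one per model) or
#'   a single combined data frame.
#' @param strict Error when the reports' tissue sets differ (default TRUE;
#'   rows missing from some model are then only allowed as NA cells when
#'   FALSE).
#' @return Data frame of class `model_comparison` with attribute `sd` (the
#'   matching ± table).
#' @export
compare_models <- function(reports, strict = TRUE) {
  combined <- if (is.data.frame(reports)) reports else do.call(rbind, reports)
  stopifnot(nrow(combined) > 0)
  models <- unique(combined$model)
  keys <- unique(combined[, c("tissue", "target", "label")])
  keys <- keys[order(keys$target, keys$label), , drop = FALSE]
  if (strict) {
    sets <- split(paste(combined$tissue, combined$target), combined$model)
    full <- paste(keys$tissue, keys$target)
    for (m in models) {
      diffset <- setdiff(full, sets[[m]])
      if (length(diffset) > 0) {
        stop("model '", m, "' is missing rows for: ",
             paste(diffset, collapse = "; "),
             " (use strict = FALSE to allow NA cells)")
      }
    }
  }
  mape <- matrix(NA_real_, nrow(keys), length(models),
                 dimnames = list(NULL, models))
  sd_m <- mape
  for (i in seq_len(nrow(keys))) {
    sub <- combined[combined$tissue == keys$tissue[i] &
                      combined$target == keys$target[i], ]
    mape[i, sub$model] <- sub$mape
    sd_m[i, sub$model] <- sub$ape_sd
  }
  best <- apply(mape, 1, function(r) {
    if (all(is.na(r))) return(NA_character_)
    paste(models[which(r <= min(r, na.rm = TRUE) + 1e-12)], collapse = ",")
  })
  out <- cbind(keys[, c("tissue", "target")], as.data.frame(mape),
               best = best, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "sd") <- cbind(keys[, c("tissue", "target")], as.data.frame(sd_m))
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> MAPE (%) per tissue; 'best' flags row minima\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Render a comparison table as Markdown
#'
#' @param comparison A `model_comparison`.
#' @param digits Digits for MAPE values.
#' @return Character vector of Markdown lines (invisibly printable via
#'   `cat(..., sep = "\n")`); best cells are bolded.
#' @export
comparison_markdown <- function(comparison, digits = 2) {
  models <- setdiff(names(comparison), c("tissue", "target", "best"))
  sd_tab <- attr(comparison, "sd")
  header <- paste0("| Tissue | Target | ", paste(models, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---|", length(models) + 2), collapse = ""))
  rows <- vapply(seq_len(nrow(comparison)), function(i) {
    flagged <- strsplit(comparison$best[i], ",")[[1]]
    cells <- vapply(models, function(m) {
      v <- comparison[i, m]
      if (is.na(v)) return("-")
      s <- sprintf(paste0("%.", digits, "f ± %.", digits, "f"), v, sd_tab[i, m])
      if (m %in% flagged) paste0("**", s, "**") else s
    }, character(1))
    paste0("| ", comparison$tissue[i], " | ", comparison$target[i], " | ",
           paste(cells, collapse = " | "), " |")
  }, character(1))
  c(header, sep, rows)
}
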