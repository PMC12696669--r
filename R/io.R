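## Shared plumbing: dataset serialisation (plain-text store), optional
## NIfTI import/export with a mask, and the staged pipeline orchestrator.
##
## Canonical on-disk layout: one directory per collection, with one
## tab-separated matrix per subject/run (`sub<k>_run<j>.tsv`, voxels x
## timepoints, no headers) and a JSON sidecar `meta.json` carrying TR,
## identifiers and the originating seed. Voxel ordering is 0-based
## row-major within the mask and recorded in the metadata.

#' Write BOLD datasets to a plain-text store
#'
#' @param datasets list of [bold_dataset()] objects.
#' @param dir output directory (created if needed).
#' @param extra named list merged into the JSON metadata (e.g. seed).
#' @return `dir`, invisibly.
#' @export
write_fmri <- function(datasets, dir, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(tr_seconds = datasets[[1]]$tr_seconds,
               n_voxels = nrow(datasets[[1]]$data),
               voxel_order = "0-based row-major within mask",
               files = list())
  for (d in datasets) {
    fn <- sprintf("sub%s_run%s.tsv", d$subject_id, d$run_id)
    utils::write.table(d$data, file.path(dir, fn), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    meta$files[[length(meta$files) + 1L]] <-
      list(file = fn, subject_id = d$subject_id, run_id = d$run_id)
  }
  meta <- utils::modifyList(meta, extra)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read BOLD datasets
#'
#' Reads either a plain-text store written by [write_fmri()] or a 4-D
#' NIfTI volume with a 3-D mask (requires the `RNifti` package); masked
#' voxels are extracted in 0-based row-major order.
#'
#' @param path store directory, or a NIfTI file.
#' @param mask optional NIfTI mask file (NIfTI route only).
#' @param tr_seconds TR override; required when a NIfTI header carries no
#'   usable time step.
#' @return list of [bold_dataset()] objects.
#' @export
read_fmri <- function(path, mask = NULL, tr_seconds = NULL) {
  if (dir.exists(path)) {
    meta_file <- file.path(path, "meta.json")
    if (!file.exists(meta_file)) stop("read_fmri: no meta.json in ", path)
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    tr <- if (!is.null(tr_seconds)) tr_seconds else meta$tr_seconds
    if (is.null(tr)) stop("read_fmri: TR missing and no override given")
    files <- meta$files
    return(lapply(seq_len(nrow(files)), function(i) {
      m <- as.matrix(utils::read.table(file.path(path, files$file[i]),
                                       sep = "\t"))
      dimnames(m) <- NULL
      bold_dataset(m, subject_id = files$subject_id[i],
                   run_id = files$run_id[i], tr_seconds = tr)
    }))
  }
  if (!file.exists(path)) stop("read_fmri: no such path: ", path)
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("read_fmri: reading NIfTI requires the RNifti package")
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 4) stop("read_fmri: expected a 4-D NIfTI volume")
  if (is.null(mask)) stop("read_fmri: a 3-D mask is required for NIfTI input")
  msk <- RNifti::readNifti(mask)
  if (!identical(dim(msk)[1:3], dm[1:3]))
    stop("read_fmri: mask grid does not match the data grid")
  keep <- which(aperm(array(msk > 0, dim(msk)), c(3, 2, 1)))
  ## row-major (x fastest in storage -> transpose axes) voxel ordering
  arr <- aperm(img[, , , , drop = FALSE], c(3, 2, 1, 4))
  flat <- matrix(arr, prod(dm[1:3]), dm[4])
  data <- flat[keep, , drop = FALSE]
  tr <- tr_seconds
  if (is.null(tr)) {
    pd <- attr(img, "pixdim")
    if (!is.null(pd) && length(pd) >= 4 && pd[4] > 0) tr <- pd[4]
  }
  if (is.null(tr)) stop("read_fmri: TR missing from header; pass `tr_seconds`")
  list(bold_dataset(data, subject_id = 1L, run_id = 1L, tr_seconds = tr))
}

#' Run the staged analysis pipeline
#'
#' Executes the selected stages in order (`simulate`, `fit`, `netmat`,
#' `bench`) on a simulated study, writing each stage's artefacts and a
#' manifest (stage list, seed, file hashes) under `out_dir`. Stages are
#' idempotent: a stage whose artefact already exists is skipped unless
#' `overwrite = TRUE`, so deleting one intermediate re-runs only the stages
#' downstream of it.
#'
#' @param config a [sim_config()].
#' @param out_dir artefact directory.
#' @param stages character subset of `c("simulate", "fit", "netmat",
#'   "bench")`, executed in canonical order.
#' @param n_modes modes for the decomposition stages.
#' @param control a [pfm_control()].
#' @param overwrite re-run stages whose artefacts exist.
#' @return the manifest (also written as `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "fit", "netmat", "bench"),
                         n_modes = config$n_modes,
                         control = pfm_control(seed = config$seed),
                         overwrite = FALSE) {
  stages <- match.arg(stages, c("simulate", "fit", "netmat", "bench"),
                      several.ok = TRUE)
  order_all <- c("simulate", "fit", "netmat", "bench")
  stages <- order_all[order_all %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(...) file.path(out_dir, ...)
  manifest <- list(seed = config$seed, stages = list())
  done <- function(name, files) {
    manifest$stages[[name]] <<- list(
      complete = TRUE, files = files,
      md5 = as.list(tools::md5sum(file.path(out_dir, files))))
  }

  sim <- NULL
  load_sim <- function() {
    if (is.null(sim)) sim <<- simulate_modes(config, seed = config$seed)
    sim
  }

  if ("simulate" %in% stages) {
    if (overwrite || !dir.exists(art("data"))) {
      write_fmri(load_sim()$datasets, art("data"),
                 extra = list(seed = config$seed))
    }
    done("simulate", file.path("data", "meta.json"))
  }
  fit <- NULL
  if (any(c("fit", "netmat", "bench") %in% stages)) {
    if (overwrite || !file.exists(art("group_maps.tsv"))) {
      if (!dir.exists(art("data")))
        stop("run_pipeline: stage `fit` needs the `data/` artefact; run ",
             "`simulate` first")
      datasets <- read_fmri(art("data"))
      fit <- pfm(datasets, n_modes = n_modes, control = control)
      utils::write.table(fit$group_maps, art("group_maps.tsv"), sep = "\t",
                         row.names = FALSE, col.names = FALSE)
    }
    done("fit", "group_maps.tsv")
  }
  if ("netmat" %in% stages) {
    if (overwrite || !file.exists(art("snet.tsv"))) {
      gm <- as.matrix(utils::read.table(art("group_maps.tsv"), sep = "\t"))
      sn <- snet(gm)
      utils::write.table(sn$values, art("snet.tsv"), sep = "\t",
                         row.names = FALSE, col.names = FALSE)
    }
    done("netmat", "snet.tsv")
  }
  if ("bench" %in% stages) {
    if (overwrite || !file.exists(art("recovery.csv"))) {
      gm <- as.matrix(utils::read.table(art("group_maps.tsv"), sep = "\t"))
      truth <- load_sim()$truth
      rep <- score_recovery(list(group_maps = gm, method = "PFM"), truth)
      utils::write.csv(as.data.frame(rep), art("recovery.csv"),
                       row.names = FALSE)
    }
    done("bench", "recovery.csv")
  }
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
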