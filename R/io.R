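#' Load a masked imaging study from disk
#'
#' Reads one co-registered NIfTI volume per subject plus a NIfTI mask, and a
#' delimited covariate table with a header row (one row per subject, same
#' order as the volumes). The image block `S` contains, per subject, the
#' intensities at the mask's retained voxels in the domain's documented
#' order, so coefficient images are reconstructible with [as_image()].
#'
#' Two-level categorical covariates (e.g. sex, diabetes, smoking) are 0/1
#' encoded with the alphabetically first level as 0; covariates with more
#' than two non-numeric levels are rejected. Missing values are reported per
#' cell and never imputed.
#'
#' @param volumes Character vector of NIfTI file paths, one per subject.
#' @param mask Path to a NIfTI mask volume (nonzero = keep) with the same
#'   shape as the subject volumes.
#' @param covariates Path to a delimited text file (TSV or CSV by
#'   extension) with a header row.
#' @param x_columns Optional character vector restricting which covariate
#'   columns enter `X`.
#' @return List with `S` (n x N intensity matrix), `X` (n x p numeric
#'   covariate matrix with column names), `domain` (an [image_domain()])
#'   and `subjects` (volume basenames).
#' @export
load_study <- function(volumes, mask, covariates, x_columns = NULL) {
  for (f in c(volumes, mask, covariates))
    if (!file.exists(f)) stop("file not found: ", f)
  mask_img <- RNifti::readNifti(mask)
  mshape <- dim(mask_img)
  domain <- image_domain(mshape, mask = as.array(mask_img) != 0)
  keep <- which(domain$mask)
  S <- matrix(0, length(volumes), domain$n_points)
  for (i in seq_along(volumes)) {
    vol <- RNifti::readNifti(volumes[i])
    if (!identical(dim(vol), mshape))
      stop("volume ", volumes[i], " has shape ",
           paste(dim(vol), collapse = "x"), " but the mask is ",
           paste(mshape, collapse = "x"))
    S[i, ] <- as.numeric(vol)[keep]
  }
  tab <- read_covariates(covariates)
  if (nrow(tab) != length(volumes))
    stop("covariate table has ", nrow(tab), " rows but there are ",
         length(volumes), " volumes")
  if (!is.null(x_columns)) {
    missing_cols <- setdiff(x_columns, names(tab))
    if (length(missing_cols))
      stop("covariate columns not found: ",
           paste(missing_cols, collapse = ", "))
    tab <- tab[, x_columns, drop = FALSE]
  }
  X <- encode_covariates(tab)
  list(S = S, X = X, domain = domain,
       subjects = basename(volumes))
}

read_covariates <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# numeric-encode a covariate data frame; 2-level strings become 0/1 by
# alphabetical order of the levels; missing cells are reported, not imputed
encode_covariates <- function(tab) {
  na_cells <- which(is.na(tab), arr.ind = TRUE)
  if (nrow(na_cells))
    stop("missing covariate values at (row, column): ",
         paste(apply(na_cells, 1L, function(rc)
           paste0("(", rc[1L], ", ", names(tab)[rc[2L]], ")")),
           collapse = ", "))
  cols <- lapply(names(tab), function(nm) {
    v <- tab[[nm]]
    if (is.numeric(v)) return(as.numeric(v))
    lev <- sort(unique(as.character(v)))
    if (length(lev) > 2L)
      stop("covariate '", nm, "' has ", length(lev),
           " non-numeric levels; only binary categoricals are encoded")
    as.numeric(as.character(v) == lev[length(lev)])
  })
  X <- do.call(cbind, cols)
  colnames(X) <- names(tab)
  X
}

#' Write a per-point coefficient vector as an image file
#'
#' Embeds the N retained values into the domain geometry and writes a NIfTI
#' volume (`.nii`/`.nii.gz`), or, for 2D domains, a plain-text matrix
#' (any other extension). Unmasked points are written as 0.
#'
#' @param values Numeric vector of length `domain$n_points`.
#' @param domain The [image_domain()] the values live on.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coefficient_image <- function(values, domain, path) {
  img <- as_image(values, domain, fill = 0)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(img), path)
  } else {
    if (length(dim(img)) != 2L)
      stop("plain-text output requires a 2D domain; use a .nii path")
    utils::write.table(img, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Save a fitted sparse PLS model as an on-disk bundle
#'
#' The bundle is a directory holding the model matrices in R's portable
#' serialisation (`model.rds`) plus a human-readable `metadata.yaml` with
#' shapes, penalties, the preprocessing record and, when available, the
#' voxel ordering information needed to reconstruct coefficient images.
#'
#' @param model An [fit_spls()] model.
#' @param dir Bundle directory (created if needed).
#' @param domain Optional [image_domain()] recorded alongside the model.
#' @param extra Optional named list merged into the metadata (e.g. seed).
#' @return `dir`, invisibly.
#' @export
save_spls <- function(model, dir, domain = NULL, extra = list()) {
  stopifnot(inherits(model, "spls"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(model = model, domain = domain),
          file.path(dir, "model.rds"))
  meta <- c(list(
    package = "rbfspls",
    version = as.character(utils::packageVersion("rbfspls")),
    n = unname(model$dims[["n"]]), p = unname(model$dims[["p"]]),
    q = unname(model$dims[["q"]]), k = model$k,
    lamX = unname(model$penalties[["lamX"]]),
    lamY = unname(model$penalties[["lamY"]]),
    centered = model$preprocess$center,
    scaled_x = model$preprocess$scale_x,
    nonzero_x = unname(colSums(model$U != 0)),
    nonzero_y = unname(colSums(model$V != 0)),
    point_order = "R array order: first axis varies fastest"
  ), extra)
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Load a model bundle written by [save_spls()]
#'
#' @param dir Bundle directory.
#' @return List with `model` (an `spls` object), `domain` (possibly `NULL`)
#'   and `metadata`.
#' @export
load_spls <- function(dir) {
  rds <- file.path(dir, "model.rds")
  if (!file.exists(rds)) stop("no model bundle at ", dir)
  bundle <- readRDS(rds)
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  list(model = bundle$model, domain = bundle$domain, metadata = meta)
}
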