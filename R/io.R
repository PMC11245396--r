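## Reading tracker files, writing result bundles, checkpointing.

numFields <- function(x) suppressWarnings(!is.na(as.numeric(x)))

#' Read tracker keypoint files
#'
#' Supported dialects:
#' \describe{
#'   \item{`plain-csv`}{Flat CSV with columns `frame`, `recording`, then
#'     `<kp>_x`, `<kp>_y` (optionally `<kp>_z`) and optionally `<kp>_conf`
#'     per keypoint. This is the format written by [writeKeypointCSV()].}
#'   \item{`csv-multiheader`}{Hierarchical-header CSV as written by common
#'     markerless trackers: 2-3 header rows naming (scorer,) bodypart and
#'     coordinate (`x`/`y`/`z`/`likelihood`), one column triplet/quadruplet
#'     per keypoint, first column a frame index.}
#'   \item{`auto`}{Sniff the header: multi-header if the second line still
#'     contains non-numeric fields beyond the first column.}
#' }
#' A missing confidence/likelihood column yields all-ones confidences with
#' a warning.
#'
#' @param path CSV file path.
#' @param dialect One of `"auto"`, `"plain-csv"`, `"csv-multiheader"`.
#' @param fps Frame rate in Hz (not stored in tracker files).
#' @return A [KeypointSeries-class].
#' @export
readKeypoints <- function(path, dialect = c("auto", "plain-csv", "csv-multiheader"),
                          fps = 30) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    lines <- readLines(path, n = 3L)
    if (length(lines) < 2L) stop("malformed file: fewer than 2 lines")
    first <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
    dialect <- if (any(grepl("_x$", first))) "plain-csv" else "csv-multiheader"
  }
  if (dialect == "plain-csv") readPlainCSV(path, fps) else readMultiheaderCSV(path, fps)
}

readPlainCSV <- function(path, fps) {
  df <- read.csv(path, check.names = FALSE)
  cn <- names(df)
  xcols <- grep("_x$", cn, value = TRUE)
  if (!length(xcols))
    stop("malformed header: no '<keypoint>_x' columns in ", path)
  kp <- sub("_x$", "", xcols)
  D <- if (all(paste0(kp, "_z") %in% cn)) 3L else 2L
  T_ <- nrow(df)
  Y <- array(NA_real_, dim = c(T_, length(kp), D))
  axes <- c("x", "y", "z")[seq_len(D)]
  for (i in seq_along(kp)) for (d in seq_len(D)) {
    col <- paste0(kp[i], "_", axes[d])
    if (!col %in% cn) stop("malformed header: missing column ", col)
    Y[, i, d] <- df[[col]]
  }
  confCols <- paste0(kp, "_conf")
  if (all(confCols %in% cn)) {
    cf <- as.matrix(df[, confCols])
  } else {
    warning("no confidence columns; assuming confidence 1 everywhere")
    cf <- matrix(1, T_, length(kp))
  }
  rec <- if ("recording" %in% cn) as.character(df$recording) else "rec1"
  checkNaNs(Y, cf)
  KeypointSeries(Y, cf, fps, rec, kp)
}

readMultiheaderCSV <- function(path, fps) {
  lines <- readLines(path)
  ## header rows: leading rows whose fields beyond the first are not all numeric
  nHeader <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], ",", fixed = TRUE)[[1L]]
    if (all(numFields(f[-1L]))) break
    nHeader <- i
  }
  if (nHeader < 2L)
    stop("malformed header: expected at least 2 header rows, line ", nHeader + 1L)
  hdr <- strsplit(lines[seq_len(nHeader)], ",", fixed = TRUE)
  ncol_ <- length(hdr[[1L]])
  bodyRow <- hdr[[nHeader - 1L]]
  coordRow <- hdr[[nHeader]]
  df <- read.csv(path, skip = nHeader, header = FALSE)
  if (ncol(df) != ncol_)
    stop("malformed header: ", ncol_, " header fields but ", ncol(df),
         " data columns")
  kp <- unique(bodyRow[-1L])
  kp <- kp[kp != ""]
  coordRow <- tolower(coordRow)
  D <- if (any(coordRow == "z")) 3L else 2L
  T_ <- nrow(df)
  Y <- array(NA_real_, dim = c(T_, length(kp), D))
  cf <- matrix(NA_real_, T_, length(kp))
  axes <- c("x", "y", "z")[seq_len(D)]
  for (i in seq_along(kp)) {
    cols <- which(bodyRow == kp[i])
    for (d in seq_len(D)) {
      j <- cols[coordRow[cols] == axes[d]]
      if (length(j) != 1L)
        stop("malformed header: keypoint '", kp[i], "' lacks a unique '",
             axes[d], "' column")
      Y[, i, d] <- df[[j]]
    }
    j <- cols[coordRow[cols] %in% c("likelihood", "confidence", "conf")]
    if (length(j) == 1L) cf[, i] <- df[[j]]
  }
  if (anyNA(cf)) {
    warning("missing likelihood column(s); assuming confidence 1")
    cf[is.na(cf)] <- 1
  }
  checkNaNs(Y, cf)
  KeypointSeries(Y, cf, fps, "rec1", kp)
}

checkNaNs <- function(Y, cf) {
  nbad <- 0L
  for (d in seq_len(dim(Y)[3L]))
    nbad <- nbad + sum(!is.finite(Y[, , d]) & cf >= 0.5)
  if (nbad > 0L)
    warning(nbad, " NaN coordinate(s) with confidence >= 0.5")
  invisible(NULL)
}

fmtNum <- function(x) sprintf("%.17g", x)

#' Write a KeypointSeries as a plain CSV
#'
#' Writes the flat format understood by [readKeypoints()] dialect
#' `"plain-csv"`, with 17 significant digits so coordinates round-trip
#' bitwise.
#'
#' @param series A [KeypointSeries-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeKeypointCSV <- function(series, path) {
  Y <- coords(series); cf <- confidences(series)
  kp <- keypointNames(series)
  D <- nDims(series)
  axes <- c("x", "y", "z")[seq_len(D)]
  cols <- c("frame", "recording")
  for (k in seq_along(kp)) cols <- c(cols, paste0(kp[k], "_", axes),
                                     paste0(kp[k], "_conf"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  T_ <- nFrames(series)
  parts <- list(as.character(seq_len(T_) - 1L), recordings(series))
  for (k in seq_along(kp)) {
    for (d in seq_len(D)) parts <- c(parts, list(fmtNum(Y[, k, d])))
    parts <- c(parts, list(fmtNum(cf[, k])))
  }
  writeLines(do.call(paste, c(parts, sep = ",")), con)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' Checkpoints hold the complete model state plus the RNG state, so a Gibbs
#' chain resumed from a checkpoint continues exactly as if it had never
#' stopped. Written with R native serialization.
#'
#' @param model A [KeypointSLDS-class].
#' @param path Checkpoint file path.
#' @param extra Optional named list stored alongside the model.
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(model, path, extra = list()) {
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  saveRDS(list(model = model, rngState = rng, extra = extra,
               version = "1"), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @param restoreRNG Restore the stored RNG state (default `TRUE`), so a
#'   resumed chain reproduces the original bit for bit.
#' @return For `loadCheckpoint`, a list with `model` and `extra`.
#' @export
loadCheckpoint <- function(path, restoreRNG = TRUE) {
  ck <- readRDS(path)
  if (restoreRNG && !is.null(ck$rngState))
    assign(".Random.seed", ck$rngState, envir = globalenv())
  ck[c("model", "extra")]
}

#' Write a fitted-model result bundle
#'
#' Emits, under `outdir`: `frames.csv` (per-frame syllable, centroid and
#' heading), `checkpoint.rds` (the full model state), and `run_log.txt`
#' (seed, key hyperparameters, iteration count).
#'
#' @param model A fitted [KeypointSLDS-class].
#' @param series The [KeypointSeries-class] the model was fit to.
#' @param outdir Output directory (created if needed).
#' @param iterations Iteration count recorded in the log.
#' @return `outdir`, invisibly.
#' @export
writeResults <- function(model, series, outdir, iterations = NA_integer_) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  lt <- model@latent
  D <- ncol(lt$v)
  df <- data.frame(frame = seq_along(lt$z) - 1L,
                   recording = recordings(series),
                   syllable = lt$z)
  for (d in seq_len(D))
    df[[paste0("centroid_", c("x", "y", "z")[d])]] <- lt$v[, d]
  df$heading <- lt$h
  write.csv(df, file.path(outdir, "frames.csv"), row.names = FALSE)
  saveCheckpoint(model, file.path(outdir, "checkpoint.rds"))
  hp <- model@hyper
  log <- c(
    sprintf("seed: %s", model@seed),
    sprintf("iterations: %s", iterations),
    sprintf("N: %d  M: %d  L: %d", hp$N, hp$M, hp$L),
    sprintf("gamma: %g  alpha: %g  kappa: %g", hp$gamma, hp$alpha, hp$kappa),
    sprintf("fps: %g", fps(series)))
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' Read / write a project configuration file
#'
#' Plain `key: value` text configuration (a restricted YAML subset:
#' scalars only). Unknown keys are rejected. Round-trips losslessly.
#'
#' @param path Config file path.
#' @return For `readProjectConfig`, a named list.
#' @export
readProjectConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    key <- m[2L]; val <- trimws(m[3L])
    if (!key %in% names(defaultProjectConfig()))
      stop("unknown config key: ", key)
    tmpl <- defaultProjectConfig()[[key]]
    out[[key]] <- if (is.numeric(tmpl)) as.numeric(val) else val
  }
  cfg <- defaultProjectConfig()
  cfg[names(out)] <- out
  cfg
}

#' @rdname readProjectConfig
#' @param cfg Named list of configuration values.
#' @export
writeProjectConfig <- function(cfg, path) {
  bad <- setdiff(names(cfg), names(defaultProjectConfig()))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  vals <- vapply(cfg, function(v)
    if (is.numeric(v)) fmtNum(v) else as.character(v), character(1L))
  writeLines(paste0(names(cfg), ": ", vals), path)
  invisible(path)
}

#' @rdname readProjectConfig
#' @export
defaultProjectConfig <- function() {
  list(
    input = "keypoints.csv",
    dialect = "auto",
    fps = 30,
    anterior = "kp1",
    posterior = "kp8",
    variance_target = 0.9,
    n_states = 100,
    kappa = NA_real_,
    target_duration_ms = 400,
    arhmm_iters = 50,
    full_iters = 500,
    seed = 1,
    outdir = "results"
  )
}
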