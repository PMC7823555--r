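#' @include AllClasses.R
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
NULL

#' Construct an EpochSet
#'
#' @param signals either a channels x time x epochs numeric array, or an
#'   (nChannels * epochLen) x epochs matrix with channels varying fastest.
#' @param flashIndex integer vector in 1..12, one per epoch.
#' @param repetitionIndex integer vector, one per epoch.
#' @param characterIndex integer vector mapping epochs to character trials.
#' @param label integer 0/1 vector (or NA for unlabeled test data).
#' @param fs sampling rate in Hz.
#' @param layout the [SpellerMatrix-class] the trial indices refer to.
#' @param targets per-trial attended characters (one per distinct
#'   characterIndex), or NULL when unknown.
#' @param preprocessing named logical list of provenance flags
#'   (windowed/filtered/normalized/rebalanced).
#' @return an [EpochSet-class].
#' @export
EpochSet <- function(signals, flashIndex, repetitionIndex,
                     characterIndex = rep(1L, length(flashIndex)),
                     label = rep(NA_integer_, length(flashIndex)),
                     fs = 240, layout = spellerMatrix(), targets = NULL,
                     preprocessing = list(windowed = TRUE, filtered = FALSE,
                                          normalized = FALSE,
                                          rebalanced = FALSE)) {
  if (length(dim(signals)) == 3L) {
    d <- dim(signals)
    nChannels <- d[1L]; epochLen <- d[2L]
    signals <- matrix(signals, nrow = d[1L] * d[2L], ncol = d[3L])
  } else {
    stop("signals must be a channels x time x epochs array, or supply ",
         "nChannels/epochLen via an array", call. = FALSE)
  }
  n <- ncol(signals)
  stopIfNot(length(flashIndex) == n && length(repetitionIndex) == n &&
              length(characterIndex) == n && length(label) == n,
            "invalid argument: per-epoch fields must all have one entry per epoch")
  se <- SummarizedExperiment(
    assays = list(signals = signals),
    colData = DataFrame(flashIndex = as.integer(flashIndex),
                        repetitionIndex = as.integer(repetitionIndex),
                        characterIndex = as.integer(characterIndex),
                        label = as.integer(label)),
    metadata = list(nChannels = as.integer(nChannels),
                    epochLen = as.integer(epochLen),
                    fs = fs, layout = layout, targets = targets,
                    preprocessing = preprocessing))
  new("EpochSet", se)
}

setMethod("flashIndex", "EpochSet", function(x) colData(x)$flashIndex)
setMethod("repetitionIndex", "EpochSet", function(x) colData(x)$repetitionIndex)
setMethod("characterIndex", "EpochSet", function(x) colData(x)$characterIndex)
setMethod("epochLabels", "EpochSet", function(x) colData(x)$label)
setMethod("samplingRate", "EpochSet", function(x) metadata(x)$fs)
setMethod("spellerLayout", "EpochSet", function(x) metadata(x)$layout)
setMethod("targetChars", "EpochSet", function(x) metadata(x)$targets)

#' @describeIn EpochSet the signals as a channels x time x epochs array.
#' @param x an EpochSet.
#' @export
setMethod("epochArray", "EpochSet", function(x) {
  md <- metadata(x)
  array(assay(x, "signals"), dim = c(md$nChannels, md$epochLen, ncol(x)))
})

#' Signals of a single epoch
#'
#' @param x an [EpochSet-class].
#' @param i epoch (column) index.
#' @return a channels x time matrix.
#' @export
epochSignals <- function(x, i) {
  md <- metadata(x)
  matrix(assay(x, "signals")[, i], nrow = md$nChannels, ncol = md$epochLen)
}

setMethod("show", "EpochSet", function(object) {
  md <- metadata(object)
  flags <- md$preprocessing
  done <- names(flags)[vapply(flags, isTRUE, logical(1L))]
  cat("EpochSet:", ncol(object), "epoch(s),", md$nChannels, "channel(s) x",
      md$epochLen, "sample(s) @", md$fs, "Hz\n")
  lab <- epochLabels(object)
  if (all(is.na(lab))) cat("  labels : absent\n")
  else cat("  labels :", sum(lab == 1L, na.rm = TRUE), "positive /",
           sum(lab == 0L, na.rm = TRUE), "negative\n")
  cat("  trials :", length(unique(characterIndex(object))), "character(s)\n")
  cat("  preproc:", if (length(done)) paste(done, collapse = ", ") else "raw", "\n")
})

# Mark a preprocessing stage as done in the provenance metadata.
setProvenance <- function(x, stage) {
  metadata(x)$preprocessing[[stage]] <- TRUE
  x
}

#' Combine epoch containers
#'
#' Concatenates epochs of compatible containers; character indices of later
#' containers are shifted so trials stay distinct, and per-trial targets are
#' concatenated.
#'
#' @param ... [EpochSet-class] objects with identical geometry and metadata.
#' @return an [EpochSet-class].
#' @export
bindEpochSets <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) && !is(parts[[1L]], "EpochSet"))
    parts <- parts[[1L]]
  stopIfNot(length(parts) >= 1L, "invalid argument: no containers given")
  md <- metadata(parts[[1L]])
  sig <- do.call(cbind, lapply(parts, function(p) assay(p, "signals")))
  shift <- 0L
  ci <- integer(0); targets <- character(0)
  for (p in parts) {
    stopIfNot(metadata(p)$nChannels == md$nChannels &&
                metadata(p)$epochLen == md$epochLen,
              "invalid argument: incompatible epoch geometry")
    ci <- c(ci, characterIndex(p) + shift)
    tg <- targetChars(p)
    if (!is.null(tg)) targets <- c(targets, tg)
    shift <- shift + max(characterIndex(p))
  }
  EpochSet(array(sig, c(md$nChannels, md$epochLen, ncol(sig))),
           flashIndex = unlist(lapply(parts, flashIndex)),
           repetitionIndex = unlist(lapply(parts, repetitionIndex)),
           characterIndex = ci,
           label = unlist(lapply(parts, epochLabels)),
           fs = md$fs, layout = md$layout,
           targets = if (length(targets)) targets else NULL,
           preprocessing = md$preprocessing)
}

#' Save / load an epoch container
#'
#' Lossless round-trip of the signals and all metadata through R's
#' hierarchical binary serialization. Files written by other tools or
#' truncated in transit produce a format error rather than a crash.
#'
#' @param x an [EpochSet-class].
#' @param path file path.
#' @return \code{loadEpochs} returns the restored [EpochSet-class];
#'   \code{saveEpochs} returns \code{path} invisibly.
#' @export
saveEpochs <- function(x, path) {
  stopIfNot(is(x, "EpochSet"), "invalid argument: x must be an EpochSet")
  saveRDS(x, path)
  invisible(path)
}

#' @rdname saveEpochs
#' @export
loadEpochs <- function(path) {
  if (!file.exists(path))
    stop("not found: ", path, call. = FALSE)
  x <- tryCatch(readRDS(path),
                error = function(e) stop("format error reading '", path,
                                         "': ", conditionMessage(e),
                                         call. = FALSE))
  if (!is(x, "EpochSet"))
    stop("format error: '", path, "' does not contain an EpochSet",
         call. = FALSE)
  validObject(x)
  x
}

# ---------------------------------------------------------------------------
# Competition-format loader (plumbing; the canonical input is the simulator)
# ---------------------------------------------------------------------------

#' Load a P300 speller session in the BCI Competition III layout
#'
#' Cuts continuous multichannel recordings released in the competition's
#' matrix-of-recordings layout into raw flash-locked epochs (pre-window
#' length, unfiltered). The session may be given as an R list with fields
#' \code{Signal} (characters x samples x channels), \code{Flashing},
#' \code{StimulusCode} (both characters x samples), and optionally
#' \code{StimulusType} and \code{TargetChar}, as an .rds file of such a list,
#' or as a MATLAB .mat file (converted through the system python's scipy when
#' available).
#'
#' @param x session list or file path.
#' @param matrix the [SpellerMatrix-class] of the session.
#' @param fs sampling rate in Hz (the competition recordings use 240).
#' @param epochLen samples per epoch (default floor(0.670 * fs)).
#' @return an [EpochSet-class] of raw epochs; labels are marked absent when
#'   the session carries no StimulusType field.
#' @export
loadCompetitionSession <- function(x, matrix = spellerMatrix(), fs = 240,
                                   epochLen = as.integer(floor(0.670 * fs))) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("not found: ", x, call. = FALSE)
    x <- if (grepl("\\.mat$", x, ignore.case = TRUE)) readMatViaPython(x)
         else tryCatch(readRDS(x),
                       error = function(e) stop("format error reading '", x,
                                                "': ", conditionMessage(e),
                                                call. = FALSE))
  }
  need <- c("Signal", "Flashing", "StimulusCode")
  if (!is.list(x) || !all(need %in% names(x)))
    stop("format error: session must contain fields ",
         paste(need, collapse = ", "), call. = FALSE)
  sig <- x$Signal
  if (length(dim(sig)) != 3L)
    stop("format error: Signal must be characters x samples x channels",
         call. = FALSE)
  nChar <- dim(sig)[1L]; nSamp <- dim(sig)[2L]; nChan <- dim(sig)[3L]
  hasType <- !is.null(x$StimulusType)
  epochs <- list(); fi <- ri <- ci <- lab <- integer(0)
  for (ch in seq_len(nChar)) {
    flash <- as.numeric(x$Flashing[ch, ])
    onsets <- which(diff(c(0, flash)) == 1)           # rising edges
    codes <- as.integer(x$StimulusCode[ch, onsets])
    seen <- integer(12L)
    for (k in seq_along(onsets)) {
      on <- onsets[k]
      if (on + epochLen - 1L > nSamp)
        stop("invalid argument: flash onset ", on - 1L,
             " too close to the recording end", call. = FALSE)
      epochs[[length(epochs) + 1L]] <- t(sig[ch, on:(on + epochLen - 1L), ])
      code <- codes[k]
      seen[code] <- seen[code] + 1L
      fi <- c(fi, code); ri <- c(ri, seen[code]); ci <- c(ci, ch)
      lab <- c(lab, if (hasType) as.integer(x$StimulusType[ch, on])
               else NA_integer_)
    }
  }
  arr <- array(unlist(epochs), dim = c(nChan, epochLen, length(epochs)))
  targets <- if (!is.null(x$TargetChar))
    strsplit(paste(x$TargetChar, collapse = ""), "")[[1L]] else NULL
  EpochSet(arr, flashIndex = fi, repetitionIndex = ri, characterIndex = ci,
           label = lab, fs = fs, layout = matrix, targets = targets,
           preprocessing = list(windowed = TRUE, filtered = FALSE,
                                normalized = FALSE, rebalanced = FALSE))
}

# Convert a MATLAB v5 .mat session through the system python + scipy: arrays
# are dumped as raw little-endian doubles with a JSON shape manifest and read
# back with readBin.
readMatViaPython <- function(path) {
  py <- Sys.which("python")
  if (!nzchar(py))
    stop("reading .mat files needs a python with scipy on the PATH; ",
         "convert the session to .rds instead", call. = FALSE)
  tmp <- tempfile("mat2raw"); dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  script <- file.path(tmp, "convert.py")
  writeLines(c(
    "import json, sys, os",
    "import numpy as np",
    "from scipy.io import loadmat",
    "src, out = sys.argv[1], sys.argv[2]",
    "m = loadmat(src, squeeze_me=False)",
    "manifest = {}",
    "for k, v in m.items():",
    "    if k.startswith('__'):",
    "        continue",
    "    if isinstance(v, np.ndarray) and v.dtype.kind in 'uif':",
    "        a = np.asarray(v, dtype=np.float64)",
    "        a.tofile(os.path.join(out, k + '.bin'))",
    "        manifest[k] = {'shape': list(a.shape), 'kind': 'num'}",
    "    else:",
    "        flat = np.asarray(v).ravel()",
    "        manifest[k] = {'value': [str(s) for s in flat], 'kind': 'str'}",
    "with open(os.path.join(out, 'manifest.json'), 'w') as f:",
    "    json.dump(manifest, f)"), script)
  status <- system2(py, c(script, shQuote(path), shQuote(tmp)),
                    stdout = TRUE, stderr = TRUE)
  mf <- file.path(tmp, "manifest.json")
  if (!file.exists(mf))
    stop("format error: python/scipy could not read '", path, "': ",
         paste(status, collapse = " "), call. = FALSE)
  manifest <- jsonlite::fromJSON(mf, simplifyVector = FALSE)
  out <- list()
  for (k in names(manifest)) {
    entry <- manifest[[k]]
    if (entry$kind == "num") {
      shape <- unlist(entry$shape)
      v <- readBin(file.path(tmp, paste0(k, ".bin")), "double",
                   n = prod(shape), endian = "little")
      # numpy writes row-major; build the array with reversed dims and revert
      out[[k]] <- aperm(array(v, rev(shape)), rev(seq_along(shape)))
    } else {
      out[[k]] <- unlist(entry$value)
    }
  }
  out
}
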