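#' @include AllClasses.R
NULL

#' Default 6x6 speller layout
#'
#' Row-major 'A'..'Z', '1'..'9', '_' — the conventional spelling-matrix
#' arrangement. The layout is configurable in [spellerMatrix()].
#'
#' @return a 6x6 character matrix.
#' @export
defaultSpellerLayout <- function() {
  matrix(c(LETTERS, as.character(1:9), "_"), nrow = 6L, ncol = 6L, byrow = TRUE)
}

#' Construct a speller matrix
#'
#' @param layout a 6x6 character matrix (or a length-36 character vector read
#'   row-major) of distinct single characters. Defaults to
#'   [defaultSpellerLayout()].
#' @return a [SpellerMatrix-class] object.
#' @examples
#' m <- spellerMatrix()
#' charAt(m, 3, 3)   # "O"
#' @export
spellerMatrix <- function(layout = defaultSpellerLayout()) {
  if (is.character(layout) && is.null(dim(layout))) {
    stopIfNot(length(layout) == 36L,
              "invalid argument: layout vector must have 36 characters")
    layout <- matrix(layout, nrow = 6L, ncol = 6L, byrow = TRUE)
  }
  new("SpellerMatrix", layout = layout)
}

#' @describeIn spellerMatrix the character at a (row, column) cell.
#' @param m a [SpellerMatrix-class].
#' @param row,col cell indices in 1..6.
#' @export
charAt <- function(m, row, col) {
  stopIfNot(all(c(row, col) %in% 1:6), "invalid argument: row/col must be in 1..6")
  m@layout[row, col]
}

#' @describeIn spellerMatrix the (row, column) position of a character.
#' @param ch a single character present in the matrix.
#' @export
charPosition <- function(m, ch) {
  idx <- which(m@layout == ch)
  if (length(idx) != 1L)
    stop("invalid argument: target '", ch, "' not in the speller matrix",
         call. = FALSE)
  c(row = as.integer((idx - 1L) %% 6L + 1L),
    col = as.integer((idx - 1L) %/% 6L + 1L))
}

#' @describeIn spellerMatrix the two flash indices (row index, column index + 6)
#'   that contain a character.
#' @export
targetFlashIndices <- function(m, ch) {
  pos <- charPosition(m, ch)
  c(pos[["row"]], pos[["col"]] + 6L)
}

setMethod("show", "SpellerMatrix", function(object) {
  cat("SpellerMatrix (rows flash as indices 1-6, columns as 7-12)\n")
  for (r in 1:6) cat(" ", paste(object@layout[r, ], collapse = " "), "\n")
})

#' Build a randomized flash schedule
#'
#' Draws, for each repetition, an independent uniform-random permutation of
#' the 12 flash indices (rows 1..6, columns 7..12). Each repetition flashes
#' every row and every column exactly once; exactly 2 of the 12 flashes
#' intersect any given target character.
#'
#' @param nRepetitions number of repetitions (the paradigm uses 15 per
#'   character).
#' @param seed integer seed; the schedule is deterministic given the seed.
#' @return a [FlashSchedule-class].
#' @export
buildFlashSchedule <- function(nRepetitions, seed = 1L) {
  nRepetitions <- assertCount(nRepetitions, "nRepetitions")
  ord <- withSeed(seed, {
    t(vapply(seq_len(nRepetitions), function(i) sample.int(12L),
             integer(12L)))
  })
  new("FlashSchedule", order = ord)
}

setMethod("nRepetitions", "FlashSchedule", function(x) nrow(x@order))

setMethod("flashOrder", "FlashSchedule", function(x) x@order)

setMethod("show", "FlashSchedule", function(object) {
  cat("FlashSchedule:", nrow(object@order), "repetition(s) x 12 flashes\n")
})

#' Flattened flash sequence of a schedule
#'
#' @param schedule a [FlashSchedule-class].
#' @return integer vector of flash indices in presentation order
#'   (repetition-major), length 12 * nRepetitions.
#' @export
flashSequence <- function(schedule) as.integer(t(schedule@order))

#' Label the epochs of a character trial
#'
#' A flash event is target-positive iff its flash index equals the target's
#' row index or the target's column index + 6; every repetition therefore
#' contains exactly 2 positive and 10 negative epochs.
#'
#' @param schedule a [FlashSchedule-class].
#' @param target the attended character.
#' @param matrix the [SpellerMatrix-class] (default layout if omitted).
#' @return integer 0/1 vector, one label per flash event in presentation
#'   order.
#' @export
labelEpochs <- function(schedule, target, matrix = spellerMatrix()) {
  hits <- targetFlashIndices(matrix, target)
  as.integer(flashSequence(schedule) %in% hits)
}

#' Accumulate per-epoch detection probabilities into a score table
#'
#' Sums the detector's P300 probabilities per flash index over the first
#' \code{nRepetitionsUsed} repetitions of a character trial (Epochs in the
#' experiment sense: one repetition = 12 flashes). Summation across
#' repetitions is the standard speller accumulation and is equivalent to the
#' mean for the subsequent argmax decoding.
#'
#' @param probabilities per-epoch detection probabilities in [0, 1].
#' @param flashIndices per-epoch flash index in 1..12.
#' @param nRepetitionsUsed how many repetitions to accumulate.
#' @param repetitionIndices optional per-epoch repetition index; if omitted,
#'   epochs are assumed to be in presentation order, 12 per repetition.
#' @return a [ScoreTable-class].
#' @export
accumulateScores <- function(probabilities, flashIndices, nRepetitionsUsed,
                             repetitionIndices = NULL) {
  if (length(probabilities) != length(flashIndices))
    stop("invalid argument: probabilities and flashIndices lengths differ",
         call. = FALSE)
  stopIfNot(all(probabilities >= 0 & probabilities <= 1),
            "invalid argument: probabilities must lie in [0, 1]")
  nRepetitionsUsed <- assertCount(nRepetitionsUsed, "nRepetitionsUsed")
  if (is.null(repetitionIndices)) {
    stopIfNot(length(probabilities) %% 12L == 0L,
              "invalid argument: need repetitionIndices unless epochs come 12 per repetition")
    repetitionIndices <- rep(seq_len(length(probabilities) %/% 12L), each = 12L)
  }
  if (length(repetitionIndices) != length(probabilities))
    stop("invalid argument: repetitionIndices length differs", call. = FALSE)
  keep <- repetitionIndices <= nRepetitionsUsed
  y <- vapply(1:12, function(i)
    sum(probabilities[keep & flashIndices == i]), numeric(1L))
  new("ScoreTable", y = y, nEpochsUsed = nRepetitionsUsed)
}

setMethod("scoreVector", "ScoreTable", function(x) x@y)

setMethod("show", "ScoreTable", function(object) {
  cat("ScoreTable (", object@nEpochsUsed, "repetition(s) accumulated )\n")
  cat("  rows   :", format(round(object@y[1:6], 3)), "\n")
  cat("  columns:", format(round(object@y[7:12], 3)), "\n")
})

#' Decode the attended character from accumulated scores
#'
#' The decoded row is the argmax of the accumulated scores over flash indices
#' 1..6 and the decoded column the argmax over 7..12; the character is the
#' cell at their intersection. Ties are broken deterministically towards the
#' lowest flash index.
#'
#' @param scores a [ScoreTable-class].
#' @param matrix the [SpellerMatrix-class].
#' @return the decoded character.
#' @export
decodeCharacter <- function(scores, matrix = spellerMatrix()) {
  y <- scoreVector(scores)
  ix <- which.max(y[1:6])        # which.max takes the first (lowest) maximum
  iy <- which.max(y[7:12])
  charAt(matrix, ix, iy)
}
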