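#' Probe design description
#'
#' Describes the layout of a SELEX probe: a constant 5' adapter that must end
#' in the dinucleotide CT (the adapter terminus that can act as a partial
#' 5' border for protein binding and causes the position-bias artifact), a
#' randomized variable region, a library barcode and a constant 3' adapter.
#'
#' The default adapters are synthetic placeholders of lengths 33 and 37 nt so
#' that the assembled probe is 99 nt; real adapter sequences can be injected.
#'
#' @param adapter5 5' adapter sequence; must end in "CT".
#' @param adapter3 3' adapter sequence.
#' @param variable_length length of the randomized region (nt).
#' @param barcode_length length of the library barcode (nt).
#' @param barcodes named character vector, library label -> barcode.
#' @param total_length declared total probe length; checked against the parts.
#' @return an object of class \code{probe_design}.
#' @export
#' @examples
#' d <- probe_design()
#' nchar(assemble_probe(d, strrep("A", 25), "GATC"))  # 99
probe_design <- function(adapter5 = "GACGATCGTAGCAGGTACGAGTCATCGCAGACT",
                         adapter3 = "TCGTATGCCGTCTTCTGCTTGAAGATCGGAAGAGCAC",
                         variable_length = 25L,
                         barcode_length = 4L,
                         barcodes = c(probe1 = "GATC", probe2 = "CTAG",
                                      probe3 = "TGCA", probe4 = "ACTG",
                                      probe5 = "GTCA", probe6 = "CAGT"),
                         total_length = nchar(adapter5) + variable_length +
                           barcode_length + nchar(adapter3)) {
  check_dna(c(adapter5, adapter3), allow_n = FALSE, what = "adapter")
  if (!endsWith(adapter5, "CT")) {
    stop("adapter5 must end with the dinucleotide CT")
  }
  lens <- nchar(adapter5) + variable_length + barcode_length + nchar(adapter3)
  if (lens != total_length) {
    stop(sprintf("probe parts sum to %d nt but total_length is %d",
                 lens, total_length))
  }
  if (length(barcodes)) {
    if (any(nchar(barcodes) != barcode_length)) {
      stop("all barcodes must have length barcode_length")
    }
    if (anyDuplicated(barcodes)) stop("barcodes must be distinct")
    if (is.null(names(barcodes)) || any(names(barcodes) == "")) {
      stop("barcodes must be named by library label")
    }
    check_dna(barcodes, allow_n = FALSE, what = "barcode")
  }
  structure(list(adapter5 = adapter5, adapter3 = adapter3,
                 variable_length = as.integer(variable_length),
                 barcode_length = as.integer(barcode_length),
                 barcodes = barcodes,
                 total_length = as.integer(total_length)),
            class = "probe_design")
}

#' @export
print.probe_design <- function(x, ...) {
  cat(sprintf("Probe design: %d nt = 5' adapter (%d) + N%d + barcode (%d) + 3' adapter (%d)\n",
              x$total_length, nchar(x$adapter5), x$variable_length,
              x$barcode_length, nchar(x$adapter3)))
  cat(sprintf("Libraries: %s\n",
              paste(sprintf("%s=%s", names(x$barcodes), x$barcodes),
                    collapse = ", ")))
  invisible(x)
}

#' Read pool: the variable regions of one library at one selection round
#'
#' @param sequences character vector of uppercase sequences over A/C/G/T/N,
#'   all the same length.
#' @param round_index selection round; 0 is the initial (unselected) library.
#' @param library_label free-text label (protein + replicate).
#' @return an object of class \code{read_pool}.
#' @export
read_pool <- function(sequences, round_index = 0L, library_label = "library") {
  sequences <- as.character(sequences)
  check_dna(sequences, allow_n = TRUE, what = "read")
  if (length(sequences)) {
    L <- nchar(sequences[1])
    if (any(nchar(sequences) != L)) stop("all reads must have the same length")
  }
  if (round_index < 0) stop("round_index must be >= 0")
  structure(list(sequences = sequences,
                 round_index = as.integer(round_index),
                 library_label = library_label),
            class = "read_pool")
}

#' @export
print.read_pool <- function(x, ...) {
  cat(sprintf("Read pool '%s', round %d: %d reads of length %s\n",
              x$library_label, x$round_index, length(x$sequences),
              if (length(x$sequences)) nchar(x$sequences[1]) else "NA"))
  invisible(x)
}

read_length <- function(pool) {
  if (!length(pool$sequences)) stop("empty read pool")
  nchar(pool$sequences[1])
}

#' Assemble a full-length probe from its parts
#'
#' @param design a \code{\link{probe_design}}.
#' @param variable variable-region sequence(s).
#' @param barcode barcode sequence(s), recycled against \code{variable}.
#' @return character vector of probes \code{adapter5 + variable + barcode +
#'   adapter3}, each of the design's declared total length.
#' @export
assemble_probe <- function(design, variable, barcode) {
  if (any(nchar(variable) != design$variable_length)) {
    stop("variable region length does not match the design")
  }
  if (any(nchar(barcode) != design$barcode_length)) {
    stop("barcode length does not match the design")
  }
  paste0(design$adapter5, variable, barcode, design$adapter3)
}

#' Parse and demultiplex SELEX reads
#'
#' Reads a FASTA or FASTQ file (plain or gzip) of sequenced variable regions
#' plus barcode, splits each read into variable region (positions
#' \code{[0, variable_length)}) and barcode (the following
#' \code{barcode_length} bases; 0-based half-open coordinates), and assigns
#' reads to libraries by exact barcode match. Unmatched reads are counted,
#' never silently dropped.
#'
#' @param path FASTA/FASTQ file, or a character vector of read sequences.
#' @param design a \code{\link{probe_design}} with a non-empty barcode map.
#' @param round_index selection round the file belongs to.
#' @param format "auto", "fasta" or "fastq" (auto uses the file extension).
#' @return a list with elements \code{pools} (named list of
#'   \code{\link{read_pool}}s, one per library with at least one read),
#'   \code{assigned} (named integer counts), \code{unmatched} and
#'   \code{total}.
#' @export
parse_reads <- function(path, design, round_index = 0L, format = "auto") {
  if (length(path) == 1L && file.exists(path)) {
    if (format == "auto") {
      format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path,
                          ignore.case = TRUE)) "fastq" else "fasta"
    }
    seqs <- tryCatch(
      as.character(Biostrings::readDNAStringSet(path, format = format)),
      error = function(e) stop("malformed ", format, " input: ",
                               conditionMessage(e)))
    names(seqs) <- NULL
  } else {
    seqs <- toupper(as.character(path))
  }
  need <- design$variable_length + design$barcode_length
  short <- which(nchar(seqs) < need)
  if (length(short)) {
    stop(sprintf("record %d is shorter than variable + barcode length (%d nt)",
                 short[1], need))
  }
  check_dna(seqs, allow_n = TRUE, what = "record")
  variable <- substr(seqs, 1L, design$variable_length)
  barcode <- substr(seqs, design$variable_length + 1L, need)
  lib <- names(design$barcodes)[match(barcode, design$barcodes)]
  assigned <- table(factor(lib, levels = names(design$barcodes)))
  pools <- list()
  for (lb in names(design$barcodes)) {
    idx <- which(!is.na(lib) & lib == lb)
    if (length(idx)) {
      pools[[lb]] <- read_pool(variable[idx], round_index = round_index,
                               library_label = lb)
    }
  }
  list(pools = pools,
       assigned = setNames(as.integer(assigned), names(design$barcodes)),
       unmatched = sum(is.na(lib)),
       total = length(seqs))
}

#' Fraction of reads carrying a contaminant signature
#'
#' Selection rounds can be contaminated by carry-over of the positive-control
#' probe; this flags pools in which a fixed control signature (e.g. the
#' control's variable region) appears in more than \code{threshold} of reads.
#'
#' @param pool a \code{\link{read_pool}}.
#' @param control_signature fixed subsequence identifying the contaminant.
#' @param threshold flagging threshold on the contaminated fraction.
#' @return list with \code{fraction} and logical \code{flagged}.
#' @export
contamination_fraction <- function(pool, control_signature, threshold = 0.05) {
  if (!length(pool$sequences)) stop("empty read pool")
  frac <- mean(grepl(control_signature, pool$sequences, fixed = TRUE))
  list(fraction = frac, flagged = frac > threshold)
}

#' Write SELEX reads to FASTA or FASTQ
#'
#' FASTQ qualities are a constant 'I' placeholder (qualities are pass-through
#' only in this pipeline).
#'
#' @param pool a \code{\link{read_pool}}.
#' @param path output file; extension .fq/.fastq selects FASTQ.
#' @param barcode optional barcode appended to every read (as sequenced).
#' @return \code{path}, invisibly.
#' @export
write_reads <- function(pool, path, barcode = NULL) {
  seqs <- pool$sequences
  if (!is.null(barcode)) seqs <- paste0(seqs, barcode)
  ids <- sprintf("%s_r%d_%06d", gsub("\\s+", "_", pool$library_label),
                 pool$round_index, seq_along(seqs))
  if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) {
    qual <- strrep("I", nchar(seqs[1]))
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  } else {
    writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  }
  invisible(path)
}
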