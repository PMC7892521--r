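.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (cn in names(df)[num]) out[[cn]] <- sprintf("%.17g", df[[cn]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read an affinity table as tab-separated text
#'
#' Numeric columns are written with full precision so a round trip
#' reproduces the table exactly.
#'
#' @param aff an \code{\link{affinity_table}}.
#' @param path output file.
#' @return \code{path} (write) or an \code{\link{affinity_table}} (read).
#' @export
write_affinity_tsv <- function(aff, path) {
  df <- aff$table
  df$k <- aff$k; df$round <- aff$round; df$provenance <- aff$provenance
  .write_tsv(df, path)
}

#' @rdname write_affinity_tsv
#' @export
read_affinity_tsv <- function(path) {
  df <- .read_tsv(path)
  k <- if (nrow(df)) df$k[1] else NA_integer_
  r <- if (nrow(df)) df$round[1] else NA_integer_
  prov <- if (nrow(df)) df$provenance[1] else "unknown"
  tab <- df[, c("kmer", "count", "distinct", "expected", "raw", "affinity",
                "low_confidence")]
  structure(list(k = as.integer(k), round = as.integer(r), provenance = prov,
                 merge_revcomp = TRUE, table = tab),
            class = "affinity_table")
}

#' Write PWMs in MEME minimal motif format
#'
#' @param pwms a \code{\link{pwm}} or named list of them.
#' @param path output file.
#' @param background background letter frequencies (length 4).
#' @param nsites reported nsites per motif (cosmetic; default 20).
#' @return \code{path}, invisibly.
#' @export
write_meme <- function(pwms, path, background = rep(0.25, 4), nsites = 20) {
  if (inherits(pwms, "pwm")) pwms <- list(motif = pwms)
  if (is.null(names(pwms))) names(pwms) <- paste0("motif_", seq_along(pwms))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background[1],
                       background[2], background[3], background[4]), ""),
             con)
  for (nm in names(pwms)) {
    p <- unclass(pwms[[nm]])
    writeLines(c(sprintf("MOTIF %s", nm),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         ncol(p), nsites)), con)
    writeLines(apply(p, 2, function(col)
      paste(sprintf("%.6f", col), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs from a MEME minimal motif file
#'
#' @param path MEME minimal format file.
#' @return named list of \code{\link{pwm}}s.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  idx <- grep("^MOTIF ", lines)
  out <- list()
  for (i in idx) {
    nm <- sub("^MOTIF\\s+(\\S+).*$", "\\1", lines[i])
    hdr <- lines[i + 1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    rows <- lines[(i + 2):(i + 1 + w)]
    m <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    cols <- t(m)
    cols <- sweep(cols, 2, colSums(cols), "/")  # renormalize rounding
    out[[nm]] <- pwm(cols)
  }
  out
}

#' Serialize / deserialize a Markov background model as structured text
#'
#' @param bg a \code{\link{markov_background}}.
#' @param path output file (JSON).
#' @return \code{path} (write) or a \code{\link{markov_background}} (read).
#' @export
write_markov <- function(bg, path) {
  jsonlite::write_json(list(order = bg$order, alpha = bg$alpha,
                            initial = as.list(setNames(bg$initial,
                                                       names(bg$initial))),
                            transitions = as.data.frame(bg$transitions)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_markov
#' @export
read_markov <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  init <- unlist(x$initial)
  trans <- as.matrix(x$transitions)
  markov_background(x$order, init, trans, alpha = x$alpha)
}

#' Export pipeline result objects with a metadata sidecar
#'
#' Writes each named object to \code{<prefix>_<name>} with a format chosen by
#' class (affinity tables and data frames as TSV, PWMs as MEME minimal,
#' Markov backgrounds as JSON) plus a \code{<prefix>_metadata.json} sidecar
#' recording the seed, parameters, package version and files written.
#'
#' @param objects named list of result objects.
#' @param prefix output path prefix (directories are created).
#' @param seed seed recorded in the sidecar.
#' @param params named list of run parameters recorded in the sidecar.
#' @return invisible character vector of files written.
#' @export
export_tables <- function(objects, prefix, seed = NULL, params = list()) {
  stopifnot(is.list(objects), length(names(objects)) == length(objects))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(objects)) {
    ob <- objects[[nm]]
    f <- if (inherits(ob, "affinity_table")) {
      write_affinity_tsv(ob, sprintf("%s_%s.tsv", prefix, nm))
    } else if (inherits(ob, "pwm")) {
      write_meme(setNames(list(ob), nm), sprintf("%s_%s.meme", prefix, nm))
    } else if (inherits(ob, "markov_background")) {
      write_markov(ob, sprintf("%s_%s.json", prefix, nm))
    } else if (inherits(ob, "kmer_counts")) {
      .write_tsv(ob$table, sprintf("%s_%s.tsv", prefix, nm))
    } else if (is.matrix(ob)) {
      .write_tsv(as.data.frame(ob), sprintf("%s_%s.tsv", prefix, nm))
    } else if (is.data.frame(ob)) {
      .write_tsv(ob, sprintf("%s_%s.tsv", prefix, nm))
    } else {
      jsonlite::write_json(ob, sprintf("%s_%s.json", prefix, nm),
                           digits = NA, auto_unbox = TRUE, force = TRUE)
      sprintf("%s_%s.json", prefix, nm)
    }
    files <- c(files, f)
  }
  meta <- list(seed = seed, params = params,
               package = "cargselex",
               version = as.character(packageVersion("cargselex")),
               files = basename(files))
  jsonlite::write_json(meta, paste0(prefix, "_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, paste0(prefix, "_metadata.json")))
}

#' Serialize a dependence model as structured text
#'
#' @param model a \code{\link{dependence_model}}.
#' @param path output file (JSON).
#' @return \code{path}, invisibly.
#' @export
write_dependence <- function(model, path) {
  jsonlite::write_json(
    list(model_type = model$model_type, order = model$order,
         penalty = model$penalty, alpha = model$alpha,
         loglik = model$loglik, neff = model$neff,
         positions = lapply(model$positions, function(p)
           list(parents = p$parents, context_map = p$context_map,
                probs = as.data.frame(p$probs)))),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write / read a probe design as a JSON config
#'
#' @param design a \code{\link{probe_design}}.
#' @param path JSON file.
#' @return \code{path} (write) or a \code{\link{probe_design}} (read).
#' @export
write_probe_design <- function(design, path) {
  jsonlite::write_json(list(adapter5 = design$adapter5,
                            adapter3 = design$adapter3,
                            variable_length = design$variable_length,
                            barcode_length = design$barcode_length,
                            barcodes = as.list(design$barcodes),
                            total_length = design$total_length),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_probe_design
#' @export
read_probe_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  probe_design(adapter5 = x$adapter5, adapter3 = x$adapter3,
               variable_length = x$variable_length,
               barcode_length = x$barcode_length,
               barcodes = unlist(x$barcodes),
               total_length = x$total_length)
}
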