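#' Read mitogenome sequences from a FASTA file
#'
#' Parses a FASTA file into a `mito_records` data frame. Sequences are
#' uppercased, `U` is mapped to `T`, and every character must be an IUPAC
#' nucleotide code (or `-`). Parse failures report the offending line.
#'
#' @param path path to a FASTA file.
#' @param sample_class `"modern"` or `"ancient"`, recycled across records.
#' @param is_circular logical; mitogenomes are circular, the default.
#' @return a data frame of class `mito_records` with columns `id`,
#'   `sequence`, `is_circular`, `sample_class`, `tip_date`, `tip_date_sd`.
#' @seealso [write_fasta()], [read_tipdates()]
#' @export
read_fasta <- function(path, sample_class = "modern", is_circular = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("FASTA parse error: file is empty: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("FASTA parse error at line ", nonblank[1],
         ": expected a '>' header")
  hdr <- startsWith(trimws(lines), ">")
  bad <- which(!hdr & nzchar(trimws(lines)) &
                 grepl("[^ACGTUNRYSWKMBDHVacgtunryswkmbdhv-]",
                       trimws(lines)))
  if (length(bad))
    stop("FASTA parse error at line ", bad[1],
         ": invalid sequence character in \"",
         substr(trimws(lines[bad[1]]), 1, 30), "\"")
  idx <- cumsum(hdr)
  ids <- sub("^>\\s*", "", trimws(lines[hdr]))
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids))
    stop("FASTA parse error: duplicated record id: ",
         ids[duplicated(ids)][1])
  seqs <- vapply(seq_along(ids), function(i) {
    paste0(trimws(lines[!hdr & idx == i]), collapse = "")
  }, character(1))
  if (any(!nzchar(seqs)))
    stop("FASTA parse error: empty sequence for record ",
         ids[!nzchar(seqs)][1])
  seqs <- chartr("u", "t", seqs)
  seqs <- chartr("U", "T", toupper(seqs))
  mito_records(ids, seqs, is_circular = is_circular,
               sample_class = sample_class)
}

#' Construct a mito_records data frame
#'
#' @param id character vector of record ids.
#' @param sequence character vector of DNA sequences (IUPAC alphabet).
#' @param is_circular,sample_class,tip_date,tip_date_sd recycled metadata.
#' @return a `mito_records` data frame.
#' @export
mito_records <- function(id, sequence, is_circular = TRUE,
                         sample_class = "modern", tip_date = NA_real_,
                         tip_date_sd = NA_real_) {
  stopifnot(length(id) == length(sequence), !anyDuplicated(id))
  if (any(!nzchar(sequence))) stop("empty sequence not allowed")
  if (any(grepl("[^ACGTRYSWKMBDHVN-]", sequence)))
    stop("sequence contains non-IUPAC characters")
  bad_class <- setdiff(unique(sample_class), c("modern", "ancient"))
  if (length(bad_class))
    stop("unknown sample_class: ", bad_class[1])
  out <- data.frame(id = as.character(id), sequence = as.character(sequence),
                    is_circular = is_circular, sample_class = sample_class,
                    tip_date = tip_date, tip_date_sd = tip_date_sd,
                    stringsAsFactors = FALSE)
  class(out) <- c("mito_records", "data.frame")
  out
}

#' Write records to FASTA
#'
#' @param records a `mito_records` data frame (or anything with `id` and
#'   `sequence` columns).
#' @param path output path.
#' @param width line-wrap width for sequences.
#' @export
write_fasta <- function(records, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read tip dates (years before present) from a TSV file
#'
#' Expects a tab-separated file with a header row and columns `id`,
#' `date_ybp`, `sd`; lines starting with `#` are ignored. Modern samples may
#' be listed with date 0.
#'
#' @param path path to the TSV file.
#' @return a data frame with columns `id`, `date_ybp`, `sd`.
#' @export
read_tipdates <- function(path) {
  if (!file.exists(path)) stop("tip-date file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!startsWith(trimws(raw), "#") ]
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) <= 1L) {
    return(data.frame(id = character(), date_ybp = numeric(),
                      sd = numeric(), stringsAsFactors = FALSE))
  }
  df <- read.delim(text = raw, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("id", "date_ybp", "sd")
  if (!all(need %in% names(df)))
    stop("tip-date file must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$date_ybp <- as.numeric(df$date_ybp)
  df$sd <- as.numeric(df$sd)
  if (anyDuplicated(df$id))
    stop("duplicate id in tip-date file: ", df$id[duplicated(df$id)][1])
  if (any(is.na(df$date_ybp)))
    stop("non-numeric date_ybp in tip-date file")
  if (any(df$date_ybp < 0))
    stop("negative date_ybp in tip-date file: ", df$id[df$date_ybp < 0][1])
  df
}

#' Read / write Newick trees
#'
#' Thin wrappers around \pkg{ape} that turn silent failures into parse
#' errors. Round-trips preserve topology, branch lengths (to printed
#' precision) and labels.
#'
#' @param path file path.
#' @return `read_newick` returns an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                 error = function(e) NULL)
  if (is.null(tr)) stop("Newick parse error in ", path,
                        " (unbalanced parentheses or malformed tree)")
  tr
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Load a run configuration
#'
#' Reads a YAML configuration with a top-level integer `seed` and optional
#' nested stage sections (`clock`, `skyline`, `simulation`, paths). Every
#' stochastic operation in the package consumes a seed derived from this
#' value.
#'
#' @param path path to a YAML file.
#' @return a named list of class `run_config`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed) || !is.numeric(cfg$seed) ||
      cfg$seed != round(cfg$seed))
    stop("config must contain an integer `seed`")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps `(seed, stage)` to a 31-bit integer so each
#' pipeline stage consumes an independent, reproducible stream.
#'
#' @param seed master integer seed.
#' @param stage stage name.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}
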