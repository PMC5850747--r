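#' Read a gene-level count table and its library metadata
#'
#' The count table is tab-separated with a header row of library ids and
#' gene ids in the first column; cells must be non-negative integers (RPKM
#' tables are a distinct, float-valued artifact and are never re-read as
#' counts). Metadata must describe every library.
#'
#' @param path count table file.
#' @param meta library metadata: either a path to a tab-separated file with
#'   columns `library_id`, `sex`, `tissue`, `stage`, `replicate`, or an
#'   equivalent `data.frame`.
#' @param lengths,chrom optional paths (or named vectors) passed on to
#'   [readGeneLengths()] / [readChromMap()].
#' @return A [DosageExperiment-class].
#' @export
readCountTable <- function(path, meta, lengths = NULL, chrom = NULL) {
    raw <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character",
                             quote = "", comment.char = "")
    if (ncol(raw) < 2)
        stop("count table needs a gene-id column plus at least one library")
    gene_ids <- raw[[1]]
    if (anyDuplicated(gene_ids))
        stop("duplicate gene ids in count table: ",
             paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
    vals <- as.matrix(raw[, -1, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
    if (any(is.na(num)))
        stop("non-numeric cell(s) in count table")
    if (any(num < 0) || any(num != round(num)))
        stop("counts must be non-negative integers (found non-integer cell)")
    storage.mode(num) <- "integer"
    dimnames(num) <- list(as.character(gene_ids), colnames(raw)[-1])
    if (is.character(meta) && length(meta) == 1L)
        meta <- readLibraryMeta(meta)
    if (is.character(lengths) && length(lengths) == 1L)
        lengths <- readGeneLengths(lengths)
    if (is.character(chrom) && length(chrom) == 1L)
        chrom <- readChromMap(chrom)
    DosageExperiment(num, meta, lengths = lengths, chrom = chrom)
}

#' Read a library metadata table
#'
#' @param path tab-separated file with header `library_id`, `sex`, `tissue`,
#'   `stage`, `replicate`.
#' @return A `data.frame`, one row per library.
#' @export
readLibraryMeta <- function(path) {
    meta <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, quote = "",
                              comment.char = "")
    need <- c("library_id", "sex", "tissue", "stage", "replicate")
    miss <- setdiff(need, colnames(meta))
    if (length(miss))
        stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(meta$library_id))
        stop("duplicate library_id in metadata")
    if (!all(meta$sex %in% c("male", "female")))
        stop("sex must be 'male' or 'female'")
    if (any(meta$replicate < 1 | meta$replicate != round(meta$replicate)))
        stop("replicate must be a positive integer")
    meta
}

#' Write a count table (inverse of readCountTable)
#'
#' @param de a [DosageExperiment-class] (its `"counts"` assay is written).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(de, path) {
    cts <- SummarizedExperiment::assay(de, "counts")
    df <- data.frame(gene_id = rownames(cts), cts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write library metadata to a tab-separated file
#' @param de a [DosageExperiment-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLibraryMeta <- function(de, path) {
    cd <- as.data.frame(SummarizedExperiment::colData(de))
    utils::write.table(cd, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read FASTA sequences into a named character vector
#'
#' The id of each record is the header token before the first whitespace;
#' sequences are uppercased and line wrapping is joined. Duplicate ids and
#' empty records are errors.
#'
#' @param path FASTA file.
#' @return Named character vector, id -> sequence.
#' @export
readFastaSeqs <- function(path) {
    ss <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    if (anyDuplicated(ids))
        stop("duplicate sequence id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (any(Biostrings::width(ss) == 0))
        stop("empty sequence record(s): ",
             paste(ids[Biostrings::width(ss) == 0], collapse = ", "))
    stats::setNames(toupper(as.character(ss)), ids)
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFastaSeqs <- function(seqs, path) {
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
    invisible(path)
}

.hit_cols <- c("query_id", "subject_id", "percent_identity", "aln_length",
               "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
               "evalue", "bitscore")

#' Read 12-column tabular similarity hits
#'
#' Parses the standard 12-column tabular alignment-hit dialect
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Lines starting with `#` are skipped; any other column
#' count is an error rather than guessed at.
#'
#' @param path tab-separated hits file.
#' @return `data.frame` with one row per hit, input order preserved; numeric
#'   `percent_identity`, `evalue`, `bitscore` columns.
#' @export
readHitsTabular <- function(path) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(lines)) {
        out <- as.data.frame(stats::setNames(
            rep(list(character(0)), 12), .hit_cols))
        for (col in .hit_cols[3:12]) out[[col]] <- numeric(0)
        return(out)
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nfield <- lengths(parts)
    if (any(nfield != 12))
        stop("expected 12 tab-separated columns, found ",
             paste(unique(nfield[nfield != 12]), collapse = "/"),
             " on line(s) ", paste(which(nfield != 12), collapse = ", "))
    m <- matrix(unlist(parts), ncol = 12, byrow = TRUE)
    out <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                      stringsAsFactors = FALSE)
    for (j in 3:12) {
        v <- suppressWarnings(as.numeric(m[, j]))
        if (any(is.na(v)))
            stop("unparsable numeric field in column ", .hit_cols[j])
        out[[.hit_cols[j]]] <- v
    }
    if (any(out$evalue < 0)) stop("negative evalue")
    if (any(out$bitscore < 0)) stop("negative bitscore")
    out
}

#' Write hits in the 12-column tabular dialect
#' @param hits a hits `data.frame` as returned by [readHitsTabular()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHitsTabular <- function(hits, path) {
    utils::write.table(hits[, .hit_cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a gene-to-chromosome assignment map
#'
#' Two tab-separated columns: gene id, chromosome label. `"Z"` is reserved
#' for the sex chromosome; any other label is autosomal. Genes absent from
#' the file are unassigned (`NA` downstream) and excluded from analyses.
#' Conflicting duplicate assignments are an error; consistent duplicates are
#' collapsed.
#'
#' @param path two-column tab-separated file (no header).
#' @return Named character vector, gene id -> chromosome label.
#' @export
readChromMap <- function(path) {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            colClasses = "character", quote = "",
                            comment.char = "#")
    if (ncol(df) != 2)
        stop("chromosome map must have exactly two columns")
    dup <- unique(df[[1]][duplicated(df[[1]])])
    for (g in dup) {
        if (length(unique(df[[2]][df[[1]] == g])) > 1)
            stop("conflicting chromosome assignments for gene ", g)
    }
    df <- df[!duplicated(df[[1]]), , drop = FALSE]
    stats::setNames(df[[2]], df[[1]])
}

#' Write a chromosome map (inverse of readChromMap)
#' @param chrom named character vector; `NA` entries (unassigned) are
#'   omitted, matching the reader's absent-means-unassigned convention.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeChromMap <- function(chrom, path) {
    chrom <- chrom[!is.na(chrom)]
    utils::write.table(data.frame(names(chrom), unname(chrom)), path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}

#' Read a gene length table
#' @param path two-column tab-separated file: gene id, length in bp.
#' @return Named numeric vector.
#' @export
readGeneLengths <- function(path) {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            colClasses = c("character", "numeric"),
                            quote = "", comment.char = "#")
    if (ncol(df) != 2) stop("length table must have exactly two columns")
    if (anyDuplicated(df[[1]])) stop("duplicate gene ids in length table")
    if (any(df[[2]] <= 0)) stop("gene lengths must be positive")
    stats::setNames(df[[2]], df[[1]])
}

#' Read a YAML run configuration
#'
#' @param path YAML file; recognised keys include input paths or a
#'   `simulate:` block, `cutoffs`, `fc_thresholds`, `exclusion_modes`,
#'   `heterogametic_sex` and `output_dir` (see [runDosageAnalysis()]).
#' @return A named list.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (!is.null(cfg$heterogametic_sex) &&
        !cfg$heterogametic_sex %in% c("female", "male"))
        stop("heterogametic_sex must be 'female' or 'male'")
    cfg
}

# Plain-text stage logging with timestamps; silenced via
# options(zcomp.quiet = TRUE).
zcLog <- function(stage, ...) {
    if (isTRUE(getOption("zcomp.quiet"))) return(invisible(NULL))
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, paste0(...)))
}
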