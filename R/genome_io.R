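#' Construct a circular genome object
#'
#' The basic container for a named circular (or linear) nucleotide sequence
#' with optional feature annotations. Sequences are upper-cased and `U` is
#' mapped to `T`; characters outside `{A,C,G,T,N}` are rejected so that every
#' downstream classifier stays total.
#'
#' @param sequence Nucleotide sequence as a single character string.
#' @param id Genome identifier.
#' @param circular Logical; is the molecule circular?
#' @param source Free-text provenance (e.g. an accession number).
#' @param annotations Optional feature table, see [feature_table()].
#' @return An object of class `circular_genome` with elements `id`,
#'   `sequence`, `length`, `circular`, `source`, `annotations`.
#' @export
circular_genome <- function(sequence, id = "genome", circular = TRUE,
                            source = NULL, annotations = NULL) {
  sequence <- chartr("u", "t", toupper(sequence))
  sequence <- chartr("U", "T", sequence)
  check_dna(sequence, sprintf("genome '%s' sequence", id))
  if (!is.null(annotations)) annotations <- validate_features(annotations, nchar(sequence))
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence),
         circular = isTRUE(circular), source = source, annotations = annotations),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %s bp, %s%s\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear",
              if (is.null(x$source)) "" else paste0(" (", x$source, ")")))
  if (!is.null(x$annotations)) {
    cat(sprintf("  %d feature segments (%d features)\n",
                nrow(x$annotations), length(unique(x$annotations$feature_id))))
  }
  invisible(x)
}

#' Build a feature annotation table
#'
#' Features are stored one row per segment in 0-based half-open genome
#' coordinates on the forward strand; multi-segment features (e.g. spliced
#' CDS) share a `feature_id` and are ordered 5'->3' on the coding strand.
#'
#' @param feature_id Integer id shared by segments of one feature.
#' @param gene_name Gene name (character).
#' @param feature_type One of `CDS`, `tRNA`, `rRNA`, `ORF`.
#' @param start,end 0-based half-open segment coordinates.
#' @param strand `"+"` or `"-"`.
#' @param product Optional product description.
#' @return A `data.frame` feature table.
#' @export
feature_table <- function(feature_id, gene_name, feature_type, start, end,
                          strand = "+", product = NA_character_) {
  data.frame(feature_id = as.integer(feature_id), gene_name = gene_name,
             feature_type = feature_type, start = as.integer(start),
             end = as.integer(end), strand = strand, product = product,
             stringsAsFactors = FALSE)
}

validate_features <- function(feat, genome_length) {
  need <- c("feature_id", "gene_name", "feature_type", "start", "end", "strand")
  miss <- setdiff(need, names(feat))
  if (length(miss)) stop("annotation table lacks columns: ", paste(miss, collapse = ", "))
  if (any(feat$start < 0L) || any(feat$end > genome_length) || any(feat$start >= feat$end)) {
    stop("feature segments must satisfy 0 <= start < end <= genome length")
  }
  if (!all(feat$strand %in% c("+", "-"))) stop("feature strand must be '+' or '-'")
  ok <- c("CDS", "tRNA", "rRNA", "ORF")
  if (!all(feat$feature_type %in% ok)) {
    stop("feature_type must be one of ", paste(ok, collapse = ", "))
  }
  feat
}

#' Reverse complement of a nucleotide sequence
#'
#' @param seq Character scalar over `{A,C,G,T,N}`.
#' @return The reverse complement as a character scalar (`N` maps to `N`).
#' @export
reverse_complement <- function(seq) {
  check_dna(toupper(seq), "sequence")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' GC content of a genome or sequence
#'
#' Computed as `100 * (G + C) / (A + C + G + T)`; `N` is excluded from both
#' numerator and denominator. The result is rounded half-up to two decimals,
#' the precision at which organelle genome reports print it.
#'
#' @param x A `circular_genome` or a character sequence.
#' @return Percentage, rounded to 2 decimals.
#' @export
gc_content <- function(x) {
  seq <- if (inherits(x, "circular_genome")) x$sequence else toupper(x)
  check_dna(seq, "sequence")
  counts <- table(strsplit(seq, "", fixed = TRUE)[[1]])
  acgt <- sum(counts[intersect(names(counts), c("A", "C", "G", "T"))])
  if (acgt == 0L) stop("sequence is all N; GC content undefined")
  gc <- sum(counts[intersect(names(counts), c("G", "C"))])
  round_half_up(100 * gc / acgt, 2)
}

#' Extract a (possibly origin-spanning) slice of a circular genome
#'
#' Coordinates are 0-based half-open; `end` may exceed the genome length, in
#' which case the slice wraps across the origin (circular genomes only).
#'
#' @param genome A `circular_genome`.
#' @param start,end 0-based half-open coordinates, `0 <= start < length`.
#' @return Nucleotide string of length `end - start`.
#' @export
circular_slice <- function(genome, start, end) {
  L <- genome$length
  if (start < 0 || start >= L) stop("start out of range [0, length)")
  if (end < start) stop("end must be >= start")
  if (end <= L) return(substr(genome$sequence, start + 1L, end))
  if (!genome$circular) stop("slice beyond the end of a non-circular genome")
  if (end - start > L) stop("slice longer than the genome")
  paste0(substr(genome$sequence, start + 1L, L), substr(genome$sequence, 1L, end - L))
}

# Sequence of one (multi-segment) feature, exon-joined on the coding strand.
#' Extract the exon-joined sequence of an annotated feature
#'
#' @param genome A `circular_genome`.
#' @param feature_id Feature id present in `genome$annotations`.
#' @return Coding-strand nucleotide sequence with segments joined 5'->3'.
#' @export
feature_sequence <- function(genome, feature_id) {
  ann <- genome$annotations
  seg <- ann[ann$feature_id == feature_id, , drop = FALSE]
  if (nrow(seg) == 0L) stop("no feature with id ", feature_id)
  parts <- vapply(seq_len(nrow(seg)), function(i) {
    s <- circular_slice(genome, seg$start[i], seg$end[i])
    if (seg$strand[i] == "-") reverse_complement(s) else s
  }, character(1))
  # segments are stored in 5'->3' order on the coding strand already
  paste(parts, collapse = "")
}

#' Count annotated features by type
#'
#' Duplicated genes (e.g. chloroplast inverted-repeat copies) are counted per
#' feature record; duplicate gene names are additionally flagged.
#'
#' @param genome A `circular_genome` with annotations (may be `NULL`).
#' @return A list with `counts` (named integer vector over CDS/tRNA/rRNA/ORF),
#'   `n_features`, and `duplicated_genes` (gene names present more than once).
#' @export
annotation_summary <- function(genome) {
  types <- c("CDS", "tRNA", "rRNA", "ORF")
  ann <- genome$annotations
  if (is.null(ann) || nrow(ann) == 0L) {
    return(list(counts = setNames(integer(4), types), n_features = 0L,
                duplicated_genes = character(0)))
  }
  per_feat <- ann[!duplicated(ann$feature_id), , drop = FALSE]
  counts <- setNames(integer(4), types)
  tab <- table(per_feat$feature_type)
  counts[names(tab)] <- as.integer(tab)
  dup <- names(which(table(per_feat$gene_name) > 1))
  list(counts = counts, n_features = nrow(per_feat), duplicated_genes = dup)
}

## ---- file formats -----------------------------------------------------

#' Read a genome from FASTA or GenBank flat file
#'
#' FASTA is read with `Biostrings`; GenBank flat files are parsed directly
#' (LOCUS, FEATURES with `join`/`complement` locations, ORIGIN). CDS/tRNA/rRNA
#' features are converted to 0-based half-open coordinates.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"fasta"` or `"genbank"`.
#' @param which Record to return when the file holds several (default first).
#' @param circular Circularity flag for FASTA input (GenBank uses LOCUS).
#' @return A `circular_genome` (with annotations for GenBank input).
#' @export
read_genome <- function(path, format = c("auto", "fasta", "genbank"),
                        which = 1L, circular = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE)) "genbank" else "fasta"
  }
  if (format == "fasta") {
    set <- read_genome_set(path, circular = circular)
    if (which > length(set)) stop("record ", which, " not present in ", path)
    return(set[[which]])
  }
  read_genbank(path)
}

#' Read all records of a (multi-)FASTA file
#'
#' @inheritParams read_genome
#' @return Named list of `circular_genome` objects.
#' @export
read_genome_set <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  out <- lapply(seq_along(ss), function(i) {
    circular_genome(as.character(ss[[i]]), id = ids[i], circular = circular,
                    source = path)
  })
  setNames(out, ids)
}

# Parse a GenBank location string into a segment data.frame (0-based half-open,
# ordered 5'->3' on the coding strand).
parse_gb_location <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  parse1 <- function(s, strand) {
    if (grepl("^complement\\(", s)) {
      inner <- sub("^complement\\((.*)\\)$", "\\1", s)
      return(parse1(inner, if (strand == "+") "-" else "+"))
    }
    if (grepl("^(join|order)\\(", s)) {
      inner <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
      # split on commas not inside parentheses
      depth <- 0L; parts <- character(0); buf <- ""
      for (ch in strsplit(inner, "")[[1]]) {
        if (ch == "(") depth <- depth + 1L
        if (ch == ")") depth <- depth - 1L
        if (ch == "," && depth == 0L) { parts <- c(parts, buf); buf <- "" }
        else buf <- paste0(buf, ch)
      }
      parts <- c(parts, buf)
      segs <- do.call(rbind, lapply(parts, parse1, strand = strand))
      return(segs)
    }
    m <- regmatches(s, regexec("^(\\d+)\\.\\.(\\d+)$", s))[[1]]
    if (length(m) == 3L) {
      a <- as.integer(m[2]); b <- as.integer(m[3])
      return(data.frame(start = a - 1L, end = b, strand = strand))
    }
    if (grepl("^\\d+$", s)) {
      a <- as.integer(s)
      return(data.frame(start = a - 1L, end = a, strand = strand))
    }
    stop("cannot parse GenBank location: ", loc)
  }
  segs <- parse1(loc, "+")
  # order segments 5'->3' on the coding strand
  if (all(segs$strand == "-")) segs <- segs[order(-segs$start), , drop = FALSE]
  segs
}

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) stop("malformed GenBank file (no LOCUS line): ", path)
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  id <- locus[2]
  circular <- any(grepl("^circular$", locus, ignore.case = TRUE))

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) == 0L) stop("malformed GenBank file (no ORIGIN): ", path)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i[1]][1] else length(lines) + 1L
  seq_lines <- lines[(origin_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("empty sequence in GenBank record ", id)

  feat_i <- grep("^FEATURES", lines)
  ann <- NULL
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1L):(origin_i[1] - 1L)]
    # a new feature starts with exactly 5 spaces then a key
    starts <- grep("^ {5}\\S", block)
    feats <- list()
    for (j in seq_along(starts)) {
      from <- starts[j]
      to <- if (j < length(starts)) starts[j + 1L] - 1L else length(block)
      chunk <- block[from:to]
      key <- sub("^ {5}(\\S+).*$", "\\1", chunk[1])
      if (!key %in% c("CDS", "tRNA", "rRNA")) next
      # location may continue over lines until the first qualifier (/)
      qual_start <- grep("^ {21}/", chunk)
      loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(chunk)
      loc <- paste(c(sub("^ {5}\\S+\\s+", "", chunk[1]),
                     trimws(chunk[seq_len(loc_end)[-1]])), collapse = "")
      qual <- paste(chunk[seq_len(length(chunk)) > loc_end], collapse = " ")
      getq <- function(name) {
        m <- regmatches(qual, regexec(sprintf('/%s="([^"]*)"', name), qual))[[1]]
        if (length(m) == 2L) m[2] else NA_character_
      }
      gene <- getq("gene")
      if (is.na(gene)) gene <- getq("locus_tag")
      if (is.na(gene)) gene <- paste0(key, "_", length(feats) + 1L)
      segs <- parse_gb_location(loc)
      feats[[length(feats) + 1L]] <- feature_table(
        feature_id = length(feats) + 1L, gene_name = gene, feature_type = key,
        start = segs$start, end = segs$end, strand = segs$strand,
        product = getq("product"))
    }
    if (length(feats)) ann <- do.call(rbind, feats)
  }
  circular_genome(sequence, id = id, circular = circular, source = path,
                  annotations = ann)
}

#' Write a genome to FASTA or a minimal GenBank flat file
#'
#' The GenBank writer emits LOCUS/FEATURES/ORIGIN with 1-based inclusive
#' coordinates so that [read_genome()] round-trips sequence and feature
#' coordinates exactly.
#'
#' @param genome A `circular_genome`.
#' @param path Output path.
#' @param format `"fasta"` or `"genbank"`.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::DNAStringSet(genome$sequence)
    names(ss) <- genome$id
    Biostrings::writeXStringSet(ss, path, width = 70)
    return(invisible(path))
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   UNA",
                     genome$id, genome$length,
                     if (genome$circular) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s", genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  ann <- genome$annotations
  if (!is.null(ann) && nrow(ann)) {
    for (fid in unique(ann$feature_id)) {
      seg <- ann[ann$feature_id == fid, , drop = FALSE]
      rngs <- sprintf("%d..%d", seg$start + 1L, seg$end)
      loc <- if (nrow(seg) > 1L) paste0("join(", paste(rngs, collapse = ","), ")") else rngs
      if (all(seg$strand == "-")) {
        loc <- paste0("complement(", if (nrow(seg) > 1L)
          paste0("join(", paste(rev(rngs), collapse = ","), ")") else rngs, ")")
      }
      writeLines(sprintf("     %-16s%s", seg$feature_type[1], loc), con)
      writeLines(sprintf('                     /gene="%s"', seg$gene_name[1]), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- genome$sequence
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Write features or ORFs as GFF3
#'
#' @param features A feature table ([feature_table()]) or an ORF table from
#'   [find_orfs()].
#' @param genome The `circular_genome` the coordinates refer to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, genome, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", genome$id, genome$length), con)
  if (!is.null(features) && nrow(features)) {
    if ("orf_id" %in% names(features)) {
      type <- "ORF"
      lines <- sprintf("%s\tcmsscan\t%s\t%d\t%d\t.\t%s\t.\tID=%s;protein_length=%d",
                       genome$id, type, features$start + 1L,
                       pmin(features$end, genome$length), features$strand,
                       features$orf_id, features$protein_length)
    } else {
      lines <- sprintf("%s\tcmsscan\t%s\t%d\t%d\t.\t%s\t.\tID=f%d;Name=%s",
                       genome$id, features$feature_type, features$start + 1L,
                       features$end, features$strand, features$feature_id,
                       features$gene_name)
    }
    writeLines(lines, con)
  }
  invisible(path)
}
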