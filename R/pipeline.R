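#' Parameters for the full CMS screening pipeline
#'
#' Every tunable of the screen with its default: the ORF floor (proteins of
#' at least 101 residues, i.e. "longer than 100 aa"), presence thresholds,
#' hydropathy settings, chimera thresholds, repeat and synteny settings.
#'
#' @param min_protein_length ORF screen floor (residues).
#' @param coverage_min,identity_min Presence-call thresholds.
#' @param tm_threshold,tm_window,tm_min_segment,tm_merge_gap Hydropathy
#'   predictor settings, see [predict_tm()].
#' @param chimera_min_fragment,chimera_min_identity Chimera thresholds (nt,
#'   percent).
#' @param copy_coverage,copy_identity Core-gene-copy exclusion thresholds.
#' @param repeat_min_length Repeat inventory floor (nt).
#' @param synteny_k,synteny_max_gap,synteny_min_block Collinearity settings.
#' @param scheme A [scoring_scheme()].
#' @return A `cms_params` list.
#' @export
cms_params <- function(min_protein_length = 101L,
                       coverage_min = 0.90, identity_min = 95.0,
                       tm_threshold = 1.6, tm_window = 19L,
                       tm_min_segment = 19L, tm_merge_gap = 5L,
                       chimera_min_fragment = 100L, chimera_min_identity = 90.0,
                       copy_coverage = 0.80, copy_identity = 95.0,
                       repeat_min_length = 500L,
                       synteny_k = 31L, synteny_max_gap = 2000L,
                       synteny_min_block = 500L,
                       scheme = scoring_scheme()) {
  structure(as.list(environment()), class = "cms_params")
}

#' Run the full CMS candidate-gene screen
#'
#' Stage order: ORF calling on the CMS genome; specificity against the
#' maintainer; transmembrane prediction; chimera detection against the
#' maintainer's annotated CDS set; genomic context; parental origin (when a
#' donor genome is supplied); candidate ranking; orthologous-CDS variant
#' comparison; repeat inventory; and collinearity of the CMS genome against
#' maintainer (and donor).
#'
#' @param cms,maintainer `circular_genome` objects; both should carry CDS
#'   annotations for the variant and chimera stages.
#' @param donor Optional donor `circular_genome` (origin stage skipped when
#'   absent).
#' @param params A [cms_params()] object.
#' @param verbose Emit per-stage progress lines to stderr.
#' @return An object of class `cms_scan` with components `orfs`,
#'   `specific`, `tm`, `chimera`, `context`, `origin`, `candidates`,
#'   `snps`, `indels`, `gene_presence`, `repeats`, `synteny_maintainer`,
#'   `synteny_donor`, `params`.
#' @export
cms_scan <- function(cms, maintainer, donor = NULL, params = cms_params(),
                     verbose = TRUE) {
  say <- function(stage, n) if (verbose) message(sprintf("stage=%s n=%d", stage, n))

  orfs <- find_orfs(cms, params$min_protein_length)
  say("orfs", nrow(orfs))

  specific <- specific_orfs(cms, maintainer,
                            min_protein_length = params$min_protein_length,
                            coverage_min = params$coverage_min,
                            identity_min = params$identity_min,
                            scheme = params$scheme, orfs = orfs)
  say("specific", nrow(specific))

  tm <- predict_tm_orfs(specific, threshold = params$tm_threshold,
                        window = params$tm_window,
                        min_segment_length = params$tm_min_segment,
                        merge_gap = params$tm_merge_gap)
  say("tm", sum(tm$tm_count >= 1L))

  core <- core_gene_set(maintainer)
  chimera <- lapply(seq_len(nrow(specific)), function(i) {
    detect_chimera(specific[i, ], core,
                   min_fragment = params$chimera_min_fragment,
                   min_identity = params$chimera_min_identity,
                   copy_coverage = params$copy_coverage,
                   copy_identity = params$copy_identity,
                   scheme = params$scheme)
  })
  names(chimera) <- specific$orf_id
  say("chimera", sum(vapply(chimera, nrow, integer(1)) > 0L))

  context <- lapply(seq_len(nrow(specific)), function(i) {
    genomic_context(specific[i, ], cms$annotations, cms$length)
  })
  names(context) <- specific$orf_id
  say("context", length(context))

  origin <- NULL
  if (!is.null(donor)) {
    origin <- vapply(seq_len(nrow(specific)), function(i) {
      assign_origin(specific[i, ], donor, maintainer)
    }, character(1))
    names(origin) <- specific$orf_id
    say("origin", length(origin))
  }

  candidates <- rank_candidates(specific, tm, chimera, context, origin)
  say("candidates", sum(candidates$rank_tier == "candidate"))

  vc <- compare_annotated_cds(cms, maintainer, params$scheme)
  say("snps", nrow(vc$snps))

  repeats <- find_repeats(cms, params$repeat_min_length, k = params$synteny_k)
  say("repeats", nrow(repeats))

  syn_m <- chain_blocks(anchor_map(cms, maintainer, k = params$synteny_k),
                        cms, maintainer, max_gap = params$synteny_max_gap,
                        min_block = params$synteny_min_block,
                        scheme = params$scheme)
  say("synteny_maintainer", nrow(syn_m$blocks))
  syn_d <- NULL
  if (!is.null(donor)) {
    syn_d <- chain_blocks(anchor_map(cms, donor, k = params$synteny_k),
                          cms, donor, max_gap = params$synteny_max_gap,
                          min_block = params$synteny_min_block,
                          scheme = params$scheme)
    say("synteny_donor", nrow(syn_d$blocks))
  }

  structure(list(cms_id = cms$id, maintainer_id = maintainer$id,
                 donor_id = if (!is.null(donor)) donor$id else NULL,
                 orfs = orfs, specific = specific, tm = tm,
                 chimera = chimera, context = context, origin = origin,
                 candidates = candidates, snps = vc$snps, indels = vc$indels,
                 gene_presence = vc$presence, repeats = repeats,
                 synteny_maintainer = syn_m, synteny_donor = syn_d,
                 params = params),
            class = "cms_scan")
}

# All annotated CDS of a genome as a named character vector (exon-joined).
core_gene_set <- function(genome) {
  ann <- genome$annotations
  if (is.null(ann)) stop("genome ", genome$id, " carries no annotations")
  cds <- ann[ann$feature_type == "CDS", , drop = FALSE]
  ids <- unique(cds$feature_id)
  out <- vapply(ids, function(fid) feature_sequence(genome, fid), character(1))
  names(out) <- vapply(ids, function(fid) cds$gene_name[cds$feature_id == fid][1],
                       character(1))
  out
}

# Orthologous CDS comparison by shared gene name; unmatched genes become
# presence/absence records.
compare_annotated_cds <- function(a, b, scheme = scoring_scheme()) {
  ga <- core_gene_set(a); gb <- core_gene_set(b)
  shared <- intersect(names(ga), names(gb))
  snps <- list(); indels <- list()
  for (g in shared) {
    cmp <- compare_cds(g, ga[[g]], gb[[g]], scheme)
    if (nrow(cmp$snps)) snps[[g]] <- cmp$snps
    if (nrow(cmp$indels)) indels[[g]] <- cmp$indels
  }
  presence <- data.frame(
    gene = c(setdiff(names(ga), names(gb)), setdiff(names(gb), names(ga))),
    present_in = c(rep(a$id, length(setdiff(names(ga), names(gb)))),
                   rep(b$id, length(setdiff(names(gb), names(ga))))),
    stringsAsFactors = FALSE)
  list(snps = if (length(snps)) do.call(rbind, c(snps, make.row.names = FALSE))
         else empty_snp_table(),
       indels = if (length(indels)) do.call(rbind, c(indels, make.row.names = FALSE))
         else empty_indel_table(),
       presence = presence)
}

#' @export
print.cms_scan <- function(x, ...) {
  cat("<cms_scan>", x$cms_id, "vs maintainer", x$maintainer_id,
      if (!is.null(x$donor_id)) paste("(donor", x$donor_id, ")") else "", "\n")
  cat(sprintf("  ORFs >= floor        : %d\n", nrow(x$orfs)))
  cat(sprintf("  CMS-specific ORFs    : %d\n", nrow(x$specific)))
  cat(sprintf("  with TM segment(s)   : %d\n", sum(x$tm$tm_count >= 1L)))
  cat(sprintf("  chimeric             : %d\n",
              sum(vapply(x$chimera, nrow, integer(1)) > 0L)))
  cat(sprintf("  candidate tier       : %s\n",
              paste(x$candidates$orf_id[x$candidates$rank_tier == "candidate"],
                    collapse = ", ")))
  cat(sprintf("  coding SNPs          : %d (%d syn / %d nonsyn)\n",
              nrow(x$snps), sum(x$snps$effect == "synonymous"),
              sum(x$snps$effect == "nonsynonymous")))
  cat(sprintf("  indels in CDS        : %d\n", nrow(x$indels)))
  cat(sprintf("  repeats >= floor     : %d (%s nt)\n", nrow(x$repeats),
              paste(x$repeats$length, collapse = ", ")))
  cat(sprintf("  coverage by maintainer: %.1f%% (identity %.2f%%)\n",
              x$synteny_maintainer$coverage, x$synteny_maintainer$identity))
  if (!is.null(x$synteny_donor)) {
    cat(sprintf("  coverage by donor    : %.1f%% (identity %.2f%%)\n",
                x$synteny_donor$coverage, x$synteny_donor$identity))
  }
  invisible(x)
}

#' @export
summary.cms_scan <- function(object, ...) {
  x <- object
  print(x)
  cat("\nCandidate report:\n")
  print(x$candidates, row.names = FALSE)
  if (nrow(x$snps)) {
    cat("\nCoding substitutions:\n")
    print(x$snps, row.names = FALSE)
  }
  if (nrow(x$indels)) {
    cat("\nCDS indels:\n")
    print(x$indels, row.names = FALSE)
  }
  invisible(x)
}
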