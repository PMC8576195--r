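#' Define a single SNP for the analysis panel
#'
#' A SNP definition records the variant's identity (rsID, gene), its two
#' alleles, which allele is counted as the risk (effect) allele, an optional
#' external log-odds weight for weighted risk scoring, and a `flip` flag for
#' loci at which the nominal risk allele is treated as protective when coding
#' dosages for risk scores.
#'
#' Alleles are free-form symbols: conventional bases (`"A"`, `"G"`, ...) or
#' abstract labels such as `"DEL"` for an indel, so loci like the ABO
#' exon-6 single-base deletion can be represented without committing to a
#' strand or a reference sequence.
#'
#' @param snp_id rsID string, e.g. `"rs6025"`.
#' @param gene Gene symbol used for labelling output.
#' @param alleles Character vector of length 2: the two allele symbols, in
#'   the order (non-risk, risk) is *not* required -- orientation is carried
#'   by `risk_allele`.
#' @param risk_allele One of `alleles`; the allele whose copies are counted
#'   as dosage 0/1/2.
#' @param weight Optional external per-allele log-odds weight (natural-log
#'   odds ratio) used by the weighted genetic risk score; `NA` if none is
#'   available.
#' @param flip Logical; if `TRUE` the risk allele is treated as protective
#'   when coding dosages for risk scores (dosage d becomes 2 - d).
#' @return A one-row `data.frame` with class `"snp_def"`.
#' @seealso [snp_panel()], [default_snp_panel()]
#' @export
snp_def <- function(snp_id, gene, alleles, risk_allele, weight = NA_real_,
                    flip = FALSE) {
  stopifnot(is.character(snp_id), length(snp_id) == 1L,
            is.character(alleles), length(alleles) == 2L,
            length(risk_allele) == 1L)
  if (!risk_allele %in% alleles) {
    stop("risk allele '", risk_allele, "' for ", snp_id,
         " is not one of the declared alleles (",
         paste(alleles, collapse = "/"), ")", call. = FALSE)
  }
  if (!is.na(weight) && !is.finite(weight)) {
    stop("weight for ", snp_id, " must be finite or NA", call. = FALSE)
  }
  out <- data.frame(
    snp_id = snp_id, gene = gene,
    allele1 = alleles[1L], allele2 = alleles[2L],
    risk_allele = risk_allele,
    weight = as.numeric(weight), flip = isTRUE(flip),
    stringsAsFactors = FALSE
  )
  class(out) <- c("snp_def", "data.frame")
  out
}

#' Assemble SNP definitions into a panel
#'
#' @param ... One or more objects created by [snp_def()].
#' @return A `data.frame` with class `"snp_panel"`, one row per SNP.
#' @export
snp_panel <- function(...) {
  defs <- list(...)
  if (length(defs) == 1L && is.list(defs[[1L]]) &&
      !inherits(defs[[1L]], "data.frame")) {
    defs <- defs[[1L]]
  }
  stopifnot(length(defs) >= 1L)
  out <- do.call(rbind, lapply(defs, function(d) {
    stopifnot(inherits(d, "snp_def"))
    as.data.frame(d)
  }))
  if (anyDuplicated(out$snp_id)) {
    stop("duplicated snp_id in panel", call. = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("snp_panel", "data.frame")
  out
}

#' The default six-SNP prothrombotic panel
#'
#' Five established prothrombotic variants (prothrombin G20210A in F2,
#' factor V Leiden, FGG rs2066865, F11 rs2036914 and the ABO exon-6
#' deletion) plus the SERPINC1 antithrombin Budapest 3 founder mutation
#' rs121909567.
#'
#' The ABO locus is modelled abstractly with alleles `C`/`DEL`; the
#' deletion-bearing allele is the risk orientation here, which is the
#' orientation under which the published population frequencies of the
#' locus are internally consistent with its genotype counts.
#'
#' Weights are per-allele natural-log odds ratios used by the weighted
#' genetic risk score. No published external weight exists for
#' rs121909567, so it carries none and is excluded from weighted scores.
#' The shipped weights for the other five SNPs are illustrative
#' placeholders on the scale of published VTE effect sizes; replace them
#' via a SNP configuration file ([read_snp_config()]) when an external
#' weight source is chosen.
#'
#' @return A six-row [snp_panel()].
#' @export
default_snp_panel <- function() {
  snp_panel(
    snp_def("rs121909567", "SERPINC1", c("G", "A"), "A"),
    snp_def("rs1799963", "F2", c("G", "A"), "A", weight = log(2.8)),
    snp_def("rs2036914", "F11", c("T", "C"), "C", weight = log(1.35)),
    snp_def("rs2066865", "FGG", c("G", "A"), "A", weight = log(1.25)),
    snp_def("rs6025", "F5", c("C", "T"), "T", weight = log(4.2)),
    snp_def("rs8176719", "ABO", c("C", "DEL"), "DEL", weight = log(1.5))
  )
}

#' Read a SNP panel from a YAML configuration file
#'
#' The file holds a top-level `snps:` list; each entry has `snp_id`, `gene`,
#' `alleles` (length-2 list), `risk_allele` and optionally `weight`
#' (natural-log odds ratio) and `flip`.
#'
#' @param path Path to the YAML file.
#' @return A [snp_panel()].
#' @export
read_snp_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$snps)) stop("SNP config lacks a 'snps' list", call. = FALSE)
  defs <- lapply(cfg$snps, function(s) {
    snp_def(
      snp_id = s$snp_id, gene = s$gene,
      alleles = as.character(unlist(s$alleles)),
      risk_allele = s$risk_allele,
      weight = if (is.null(s$weight)) NA_real_ else as.numeric(s$weight),
      flip = isTRUE(s$flip)
    )
  })
  snp_panel(defs)
}

#' Write a SNP panel to a YAML configuration file
#'
#' @param panel A [snp_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_config <- function(panel, path) {
  stopifnot(inherits(panel, "snp_panel"))
  snps <- lapply(seq_len(nrow(panel)), function(i) {
    s <- list(
      snp_id = panel$snp_id[i], gene = panel$gene[i],
      alleles = c(panel$allele1[i], panel$allele2[i]),
      risk_allele = panel$risk_allele[i]
    )
    if (!is.na(panel$weight[i])) s$weight <- panel$weight[i]
    if (panel$flip[i]) s$flip <- TRUE
    s
  })
  yaml::write_yaml(list(snps = snps), path, precision = 15)
  invisible(path)
}
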