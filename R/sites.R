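#' Modified mitochondrial sites analysed by the pipeline
#'
#' Returns the annotation table of the 15 mtDNA positions (rCRS, 1-based) at
#' which m1A/m1G modification level is inferred from RNA-seq mismatch
#' proportions: the 13 mt-tRNA position-9 ("P9") sites, position 2617 in
#' \emph{MT-RNR2} and position 13710 in \emph{MT-ND5}. The m1G modifications
#' occur at positions 3238 and 4271; all other sites carry m1A. Eleven of the
#' P9 sites (all but 3238 and 15896) additionally contribute to the averaged
#' P9 phenotype.
#'
#' @return A data.frame with columns \code{position}, \code{ref} (rCRS
#'   reference base), \code{category} (\code{tRNA_P9}, \code{RNR2_2617} or
#'   \code{ND5_13710}), \code{mod_type} (\code{m1A}/\code{m1G}), \code{gene}
#'   (host gene label) and \code{in_p9_average} (logical).
#' @export
mod_sites <- function() {
  p9_pos <- c(585L, 1610L, 3238L, 4271L, 5520L, 7526L, 8303L, 9999L,
              10413L, 12146L, 12274L, 14734L, 15896L)
  p9_gene <- c("MT-TF", "MT-TV", "MT-TL1", "MT-TI", "MT-TW", "MT-TD",
               "MT-TK", "MT-TG", "MT-TR", "MT-TH", "MT-TS2", "MT-TE",
               "MT-TT")
  # A at m1A sites, G at the two m1G sites (3238, 4271)
  ref <- ifelse(p9_pos %in% c(3238L, 4271L), "G", "A")
  avg11 <- c(585L, 1610L, 4271L, 5520L, 7526L, 8303L, 9999L, 10413L,
             12146L, 12274L, 14734L)
  out <- data.frame(
    position = c(p9_pos, 2617L, 13710L),
    ref = c(ref, "A", "A"),
    category = c(rep("tRNA_P9", 13L), "RNR2_2617", "ND5_13710"),
    mod_type = c(ifelse(p9_pos %in% c(3238L, 4271L), "m1G", "m1A"),
                 "m1A", "m1A"),
    gene = c(p9_gene, "MT-RNR2", "MT-ND5"),
    in_p9_average = c(p9_pos %in% avg11, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  out
}

#' Phenotype column labels of the methylation matrix
#'
#' The 16 phenotypes analysed: one per modified position plus the averaged
#' P9 measure.
#' @return Character vector of length 16.
#' @export
phenotype_names <- function() {
  s <- mod_sites()
  c(paste0("p", s$position[s$category == "tRNA_P9"]), "P9_avg",
    "p2617", "p13710")
}

#' tRNA P9 sites with an mRNA/rRNA gene immediately 5' of the tRNA
#'
#' The nine adjacency pairs used when testing whether P9 methylation levels
#' relate to the expression of the gene found immediately upstream of the
#' host tRNA on the polycistronic mitochondrial transcript.
#'
#' @return A data.frame with columns \code{position} (the tRNA P9 site),
#'   \code{trna_letter} (one-letter tRNA code) and \code{upstream_gene}.
#' @export
adjacency_pairs <- function() {
  data.frame(
    position = c(1610L, 3238L, 4271L, 5520L, 8303L, 9999L, 10413L,
                 12146L, 15896L),
    trna_letter = c("V", "L1", "I", "W", "K", "G", "R", "H", "T"),
    upstream_gene = c("MT-RNR1", "MT-RNR2", "MT-ND1", "MT-ND2", "MT-CO2",
                      "MT-CO3", "MT-ND3", "MT-ND4", "MT-CYB"),
    stringsAsFactors = FALSE
  )
}
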