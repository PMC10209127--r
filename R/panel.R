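#' Built-in CHDM gene/hotspot panel
#'
#' A small panel of clonal haematopoiesis driver genes and recurrent protein
#' changes used by the synthetic-cohort generator. It mimics a targeted assay
#' covering the whole of *DNMT3A* plus established hotspots in other CH genes;
#' sampling weights favour the genes that dominate real CH call sets
#' (*DNMT3A*, *TET2*, *ASXL1*).
#'
#' @return A data.frame with columns `gene`, `hgvs_p` and sampling `weight`.
#' @export
#' @examples
#' head(chdm_panel())
chdm_panel <- function() {
  panel <- rbind(
    data.frame(gene = "DNMT3A",
               hgvs_p = c("p.R882H", "p.R882C", "p.R882S", "p.W305*",
                          "p.Y735C", "p.R736H", "p.F755S", "p.R598*",
                          "p.Q606*", "p.S714C", "p.G543A", "p.R326C"),
               weight = c(6, 4, 1.5, 1, 1, 1, 1, 1, 1, 1, 1, 1)),
    data.frame(gene = "TET2",
               hgvs_p = c("p.Q1523*", "p.H1380Y", "p.C1263Y", "p.R544*",
                          "p.S792*", "p.I1873T"),
               weight = c(2, 1.5, 1, 1, 1, 1)),
    data.frame(gene = "ASXL1",
               hgvs_p = c("p.G646fs", "p.E635fs", "p.R693*"),
               weight = c(2, 1, 1)),
    data.frame(gene = c("JAK2", "SF3B1", "SRSF2", "TP53", "PPM1D",
                        "GNB1", "CBL", "IDH2", "KRAS", "GNAS"),
               hgvs_p = c("p.V617F", "p.K700E", "p.P95H", "p.R273H", "p.R552*",
                          "p.K57E", "p.C404Y", "p.R140Q", "p.G12D", "p.R201C"),
               weight = c(2, 1, 1, 1, 1, 1, 1, 1, 1, 1))
  )
  panel$weight <- panel$weight / sum(panel$weight)
  panel
}
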