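#!/usr/bin/env Rscript
# Optional network helper (not part of the tested core): downloads the two
# deposited GC-rich organelle genome records (mtDNA HQ874522, ptDNA
# HQ693844) from NCBI as GenBank flat files into inst/extdata/real/, where
# the published-value acceptance test and the pipeline pick them up.
#
# Usage: Rscript scripts/fetch_genomes.R [dest_dir]

dest <- commandArgs(trailingOnly = TRUE)
dest <- if (length(dest)) dest[1] else "inst/extdata/real"
dir.create(dest, recursive = TRUE, showWarnings = FALSE)
base <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
               "?db=nucleotide&rettype=gb&retmode=text&id=")
for (acc in c("HQ874522", "HQ693844")) {
  out <- file.path(dest, paste0(acc, ".gb"))
  message("fetching ", acc, " -> ", out)
  utils::download.file(paste0(base, acc), out, quiet = TRUE, mode = "wb")
  Sys.sleep(1)  # NCBI rate limit courtesy
}
message("done")
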