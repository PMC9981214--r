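# Expose the package's internal Mann-Whitney wrapper for oracle comparison.
mann_whitney_oracle_check <- function(x, y) {
  wt <- xenopurity:::mann_whitney(x, y)
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

# Minimal VCF text fixture with AD depths and population-frequency INFO keys.
write_mini_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF_DBSNP,Number=1,Type=Float,Description=\"dbSNP allele frequency\">",
    "##INFO=<ID=AF_GNOMAD,Number=1,Type=Float,Description=\"gnomAD allele frequency\">",
    "##INFO=<ID=VERT_HITS,Number=1,Type=Integer,Description=\"Vertebrate genomes carrying the allele\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\tv1\tA\tG\t.\tPASS\tAF_DBSNP=0.02;AF_GNOMAD=0.03;VERT_HITS=3\tAD\t30,20",
    "chr1\t200\tv2\tC\tT\t.\tPASS\tAF_DBSNP=0;AF_GNOMAD=0;VERT_HITS=0\tAD\t50,50",
    "chr2\t300\t.\tG\tA\t.\tPASS\tAF_DBSNP=0;AF_GNOMAD=0;VERT_HITS=0\tAD\t90,10"
  )
  writeLines(lines, path)
  path
}
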