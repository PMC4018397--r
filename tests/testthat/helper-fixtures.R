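# Printed-report fixtures built in code: the two libraries' QC
# accounting, the genome-mapped category breakdown, and the worked
# fold-change example (fetal library FC vs six-month library SMC).

CLEAN_READS_FC <- 15627457
CLEAN_READS_SMC <- 15593721

qc_fc <- function() {
  tibble::tibble(
    category = c("total_reads", "high_quality", "3'adapter_null",
                 "insert_null", "5'adapter_contaminants",
                 "smaller_than_18nt", "polyA", "clean_reads"),
    count = c(15731062, 15685279, 2683, 2119, 19517, 33482, 21, 15627457))
}

qc_smc <- function() {
  tibble::tibble(
    category = c("total_reads", "high_quality", "3'adapter_null",
                 "insert_null", "5'adapter_contaminants",
                 "smaller_than_18nt", "polyA", "clean_reads"),
    count = c(15676284, 15630959, 3257, 636, 17252, 16062, 31, 15593721))
}

categories_fc <- function() {
  tibble::tibble(
    category = c("miRNA", "exon_antisense", "exon_sense", "intron_antisense",
                 "intron_sense", "rRNA", "scRNA", "snRNA", "snoRNA", "tRNA",
                 "unann"),
    unique_count = c(4229, 892, 28465, 2087, 12410, 42174, 15, 2057, 1649,
                     8800, 214422),
    read_count = c(12740265, 965, 29875, 5792, 54645, 435237, 17, 6055,
                   7294, 54890, 2292422))
}

categories_smc <- function() {
  tibble::tibble(
    category = c("miRNA", "exon_antisense", "exon_sense", "intron_antisense",
                 "intron_sense", "rRNA", "scRNA", "snRNA", "snoRNA", "tRNA",
                 "unann"),
    unique_count = c(2679, 396, 35305, 1045, 6261, 38504, 10, 1542, 1001,
                     8510, 154687),
    read_count = c(12934004, 430, 38078, 2431, 34197, 355165, 10, 4218,
                   4476, 65835, 2154877))
}

# worked example: the muscle-specific miR-1 counts in the two libraries
MIR1_SEQ <- "TGGAATGTAAAGAAGTATGTAT"
MIR1_FC <- 1929430
MIR1_SMC <- 9986601
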