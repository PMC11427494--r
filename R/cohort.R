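#' Cohort demographics of the ten adult SMA patients
#'
#' Baseline demographic, genetic and clinical metadata of the study cohort
#' (ten adult type 2-3 SMA patients under nusinersen), bundled as fixture
#' metadata: patient code, SMA type, SMN1 variation (homozygous deletion or
#' compound heterozygous variation), SMN2 copy number, age of onset in
#' years, age range at entry, orthopedic status, and the RULM / HFMSE motor
#' scores at baseline. Ages at entry are ranges, not exact years, for
#' privacy.
#'
#' @return data frame with one row per patient.
#' @export
sma_cohort <- function() {
  utils::read.delim(
    system.file("extdata", "sma_cohort.tsv", package = "smaseq",
                mustWork = TRUE),
    stringsAsFactors = FALSE
  )
}
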