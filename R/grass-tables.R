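#' Published grass count tables
#'
#' Small packaged tables transcribing the printed per-genome duplicate
#' counts, A1/A5 compartment gene counts, A1-A5 paralogon retained-duplicate
#' counts, per-lineage rearrangement-event counts and paralogon ortholog
#' counts of the four-genome grass comparison. They serve as worked-example
#' inputs for the summary operations.
#'
#' @param name one of `"duplicate_partition"`, `"a1_a5_compartments"`,
#'   `"a1_a5_paralogon_duplicates"`, `"lineage_events"`,
#'   `"ortholog_counts"`
#' @return the table as a data.frame
#' @export
grass_table <- function(name = c("duplicate_partition",
                                 "a1_a5_compartments",
                                 "a1_a5_paralogon_duplicates",
                                 "lineage_events",
                                 "ortholog_counts")) {
  name <- match.arg(name)
  path <- system.file("extdata", "grass", paste0(name, ".tsv"),
                      package = "grasskaryo")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
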