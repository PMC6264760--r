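# Embedded benchmark: 35 flavonoids with experimental vasorelaxant EC50 (uM),
# printed pEC50, model-predicted pEC50 and residual, as published. Values are
# stored exactly as printed; arithmetic inconsistencies in the source table
# are flagged by activity_records(), never corrected.

table4_raw <- function() {
  txt <- "
compound_id,ec50_uM,pec50,predicted,residual,split
1,9.3,5.032,4.977,0.055,test
2,4.6,5.337,4.976,0.361,train
3,24.0,4.620,4.841,-0.221,train
10a,7.6,5.119,5.245,-0.126,train
10b,13.7,4.863,4.260,0.603,train
11c,19.9,4.762,4.796,-0.034,train
11d,78.7,4.104,4.048,0.056,train
11e,53.5,4.272,4.592,-0.320,train
12,42.4,4.373,4.372,0.001,train
13,20.1,4.697,4.688,0.009,train
14,34.5,4.991,5.024,-0.033,train
15,37.0,4.432,4.219,0.213,test
16,32.1,4.493,4.632,-0.139,train
17,9.4,5.027,4.558,0.469,train
18,26.9,4.570,4.295,0.275,train
19,142,3.848,3.858,-0.010,train
20,13.2,4.879,4.837,0.042,test
21,24.8,4.606,4.636,-0.030,train
22,101,3.996,4.221,-0.225,train
23,15.6,4.807,4.680,0.459,test
24,72.7,4.138,4.389,-0.251,train
25,21.3,4.672,4.789,-0.117,test
26,22.5,4.648,4.919,-0.271,test
27,89.1,4.050,3.937,0.113,train
28,42.1,4.376,4.184,0.192,train
29,102,3.991,4.116,-0.125,test
30,123,3.910,3.943,-0.033,train
31,10.7,4.971,4.937,0.034,test
32,36.8,4.434,4.389,0.045,train
33,81.7,4.088,4.065,0.023,train
34,959,3.018,3.266,-0.248,train
35,643,3.192,3.175,0.017,train
36,493,3.307,3.399,-0.092,train
37,176,3.754,3.744,0.010,train
38,51.3,4.290,3.399,0.891,train
"
  utils::read.csv(textConnection(txt), stringsAsFactors = FALSE,
                  colClasses = c(compound_id = "character"))
}

#' The embedded 35-flavonoid activity benchmark
#'
#' Activity records for the 35 flavonoids of the vasorelaxant QSAR benchmark:
#' experimental EC50 (micromolar), the pEC50 as printed in the source table,
#' the published model's predicted pEC50 and residual, and the train/test
#' split (8 compounds are marked as the external test set: 1, 15, 20, 23, 25,
#' 26, 29, 31). Values are kept exactly as printed; rows whose printed pEC50
#' disagrees with their EC50 by more than 0.01 log units carry
#' `inconsistent = TRUE` (compounds 11c and 14), and compound 23's printed
#' residual does not equal its printed pEC50 minus prediction. Such defects
#' are surfaced, never repaired.
#'
#' @return An `activity_table` data frame with 35 rows.
#' @examples
#' f <- table4_fixture()
#' nrow(f)                      # 35
#' sum(f$split == "test")       # 8
#' @export
table4_fixture <- function() {
  activity_records(table4_raw())
}

#' The embedded potency/efficacy table for the newly synthesised flavonoids
#'
#' EC50 (micromolar; `NA` where not determined) and maximal relaxation Emax
#' (percent of the phenylephrine contraction) for quercetin and the nine new
#' flavanone/chalcone derivatives assayed on precontracted rat aortic rings.
#'
#' @return Data frame with columns `compound_id`, `ec50_uM`, `emax_pct`.
#' @export
table1_fixture <- function() {
  data.frame(
    compound_id = c("quercetin", "10a", "10b", "11a", "11b",
                    "11c", "11d", "11e", "11f", "11g"),
    ec50_uM = c(244, 7.6, 13.7, NA, NA, 19.9, 78.7, 53.5, NA, NA),
    emax_pct = c(91.3, 93.1, 99.5, 66.2, 50.6, 90.3, 93.5, 93.6, 52.9, 49.1),
    stringsAsFactors = FALSE
  )
}
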