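#' @importFrom data.table as.data.table fread fwrite rbindlist dcast :=
#' @importFrom stats fft quantile sd cor density approx rnorm plogis
#' @importFrom utils modifyList
NULL

.datatable.aware <- TRUE

utils::globalVariables(c("year", "doy", "ta", "rh", "P", "rg", "o3", "co2",
                         "value", "n", ".N", ".SD"))
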