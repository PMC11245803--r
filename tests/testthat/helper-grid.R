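# One full simulation-grid run is shared by several acceptance checks;
# the determinism check performs its own second, independent run.
.gridCache <- new.env(parent = emptyenv())

fullGridRun <- function(which = 1L) {
  key <- paste0("run", which)
  if (is.null(.gridCache[[key]])) {
    .gridCache[[key]] <- runSimulationStudy(seed = 1)
  }
  .gridCache[[key]]
}
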