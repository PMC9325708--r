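# Shared setup for the analysis drivers: builds (and caches) the
# synthetic study and the molecular-stage results so the numbered
# scripts can be rerun independently. Heavy intermediates live under
# scratch/ (not part of the deliverable); tables land in results/.

library(pleioscan)

SEED <- as.integer(Sys.getenv("PLEIOSCAN_SEED", "1"))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

get_study <- function() {
  cache <- sprintf("scratch/study_%d.rds", SEED)
  if (file.exists(cache)) return(readRDS(cache))
  message("simulating the study (seed ", SEED, ") ...")
  st <- simulate_study(sim_config(seed = SEED))
  saveRDS(st, cache)
  st
}

get_molecular <- function(st = get_study()) {
  cache <- sprintf("scratch/molecular_%d.rds", SEED)
  if (file.exists(cache)) return(readRDS(cache))
  message("running the molecular stage (PCs, heritability, weights, pQTLs) ...")
  mol <- pipeline_molecular(st)
  saveRDS(mol, cache)
  mol
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  message("wrote ", path, " (", nrow(x), " rows)")
}
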