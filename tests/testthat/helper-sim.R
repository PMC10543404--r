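# Shared fixtures for the suite: one standard editing chip simulation
# (10 ng gDNA equivalent, 10% TAMRA-site editing) reused across gating
# and quantification tests.

std_chip <- chip_spec()
std_panel <- crlf2_panel()
std_conc <- gdna_copies_per_ul(10)  # ~336.7 copies/uL

sim_editing_chip <- function(fraction = 0.10, seed = 1,
                             dye = "TAMRA", conc = std_conc,
                             noise = noise_model()) {
  sp <- make_editing_species(std_panel, conc, fraction, dye)
  simulate_chip(std_panel, std_chip, sp, noise, seed = seed)
}

gate_chip <- function(sim) gate(sim$table, call_thresholds(sim$table))

# quantify one simulated chip and return the TAMRA drop-off row
quant_tamra <- function(sim, method = "difference", n_boot = 200,
                        seed = 1) {
  q <- dropoff_quantify(gate_chip(sim), std_panel, std_chip,
                        method = method, n_boot = n_boot, seed = seed)
  q$dropoff[q$dropoff$dye == "TAMRA", ]
}

# write a SAM file from hand-constructed records against an amplicon
write_test_sam <- function(ref, qnames, cigars, seqs, pos = 1L,
                           flags = 0L, path = tempfile(fileext = ".sam")) {
  n <- length(qnames)
  pos <- rep_len(pos, n); flags <- rep_len(flags, n)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", ref$name, nchar(ref$seq)))
  body <- vapply(seq_len(n), function(i)
    paste(qnames[i], flags[i], ref$name, pos[i], 60L, cigars[i], "*",
          0L, 0L, seqs[i], strrep("?", nchar(seqs[i])), sep = "\t"),
    character(1))
  writeLines(c(header, body), path)
  path
}
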