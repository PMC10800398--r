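#!/usr/bin/env Rscript
# Step 4 - the biomechanical study: the intact segment (M1) and the five
# trephine resection variants (M2-M6) under a 400 N follower load plus
# 10 Nm pure moments in six directions; L4-L5 / L3-L4 range of motion and
# maximum von Mises stress in the L4/5 annulus and adjacent endplates.
#
# Findings on the default phantom: the intact model is the stiffest in
# every direction; resections increase L4-L5 motion and disc/endplate
# stress with the extent of facet destruction, most prominently in
# extension and axial rotation; the L4 inferior endplate varies less than
# the L5 superior endplate.

suppressMessages(library(lumbosim))

cfg <- run_config(target_edge = 3, out_dir = "results")
res <- run_biomech_study(cfg)
for (d in unique(res$direction)) {
  cat("\n--", d, "--\n")
  print(res[res$direction == d,
            c("variant", "rom_L4L5", "rom_L3L4", "vm_annulus_L4L5",
              "vm_endplate_L5_superior", "vm_endplate_L4_inferior")],
        digits = 4, row.names = FALSE)
}
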