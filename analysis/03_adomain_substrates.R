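#!/usr/bin/env Rscript
# Substrate predictions for the seven adenylation domains of the
# nostocyclopeptide synthetase (NcpA1-NcpA3, NcpB1-NcpB4) from their
# nine-residue binding-pocket signatures (GrsA numbering). Each packaged
# signature self-predicts its proposed substrate at identity 1.0; the
# nearest foreign signature is reported to show code separation. The
# predicted substrate order Tyr-Gly-Gln-(Ile/Val)-Ser-(Pro/MePro)-
# (Phe/Tyr/Leu) matches the residue order of the detected peptides.

library(ncptools)

ref <- ncp_reference_code()
dir.create("results", showWarnings = FALSE)

rows <- lapply(seq_len(nrow(ref)), function(i) {
  pred <- predict_substrate(ref$signature[i], ref, top_k = 2L)
  data.frame(module = ref$module[i], signature = ref$signature[i],
             substrate = pred$substrate[1], similarity = pred$similarity[1],
             runner_up = pred$substrate[2],
             runner_up_similarity = round(pred$similarity[2], 3),
             brackets = ref$brackets[i], stringsAsFactors = FALSE)
})
tab <- do.call(rbind, rows)
write.table(tab, "results/adomain_predictions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(tab, row.names = FALSE)

cat("\nPairwise signature identities (fraction of 9 pocket residues):\n")
m <- outer(ref$signature, ref$signature,
           Vectorize(function(a, b) round(signature_similarity(a, b), 2)))
dimnames(m) <- list(ref$module, ref$module)
print(m)
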