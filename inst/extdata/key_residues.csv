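gene,reference_id,position,expected,note
oxc,O06644,56,E,mutagenesis-referenced key residue (UniProtKB)
oxc,O06644,120,Y,mutagenesis-referenced key residue (UniProtKB)
oxc,O06644,121,E,mutagenesis-referenced key residue (UniProtKB)
oxc,O06644,483,Y,mutagenesis-referenced key residue (UniProtKB)
oxc,O06644,553,S,mutagenesis-referenced key residue (UniProtKB)
oxc,O06644,555,R,mutagenesis-referenced key residue (UniProtKB)
oxdC,O34714,270,R,mutagenesis-referenced key residue (UniProtKB)
oxdC,O34714,333,E,mutagenesis-referenced key residue (UniProtKB)
oxdC,O34714,340,Y,mutagenesis-referenced key residue (UniProtKB)
frc,O06643,17,Q,mutagenesis-referenced key residue (UniProtKB)
frc,O06643,48,W,mutagenesis-referenced key residue (UniProtKB)
frc,O06643,169,D,mutagenesis-referenced key residue (UniProtKB)
frc,O06643,259,G,mutagenesis-referenced key residue (UniProtKB)
frc,O06643,260,G,mutagenesis-referenced key residue (UniProtKB)
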