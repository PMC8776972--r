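"""Batch Morgan/circular fingerprint generation.

Reads a TSV of (id, SMILES) pairs and writes a TSV of
(id, status, comma-separated set-bit indices).  status is OK or ERROR;
ERROR rows carry the offending SMILES in the third column instead of bits.
Invoked by the R package as a single batched subprocess per node set.
"""
import argparse
import sys


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--radius", type=int, default=2)
    ap.add_argument("--nbits", type=int, default=2048)
    ap.add_argument("--infile", required=True)
    ap.add_argument("--outfile", required=True)
    args = ap.parse_args()

    from rdkit import Chem, RDLogger
    from rdkit.Chem import rdFingerprintGenerator

    RDLogger.DisableLog("rdApp.*")
    gen = rdFingerprintGenerator.GetMorganGenerator(
        radius=args.radius, fpSize=args.nbits)

    with open(args.infile) as fin, open(args.outfile, "w") as fout:
        for line in fin:
            line = line.rstrip("\n")
            if not line:
                continue
            ident, smiles = line.split("\t", 1)
            mol = Chem.MolFromSmiles(smiles)
            if mol is None:
                fout.write(f"{ident}\tERROR\t{smiles}\n")
                continue
            bits = gen.GetFingerprint(mol).GetOnBits()
            fout.write(f"{ident}\tOK\t{','.join(str(b) for b in bits)}\n")
    return 0


if __name__ == "__main__":
    sys.exit(main())
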