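"""Hashed circular (Morgan) fingerprint bit positions for a SMILES table.

Usage: python ecfp_bits.py <tsv: id \t smiles> <radius> <n_bits>
Writes one line per input row: id \t comma-separated 0-based bit positions,
or id \t FAIL when the SMILES does not parse.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def main(path, radius, n_bits):
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=n_bits)
    with open(path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            drug_id, smiles = line.split("\t", 1)
            mol = Chem.MolFromSmiles(smiles)
            if mol is None:
                print(f"{drug_id}\tFAIL")
                continue
            bits = sorted(gen.GetFingerprint(mol).GetOnBits())
            print(f"{drug_id}\t{','.join(map(str, bits))}")


if __name__ == "__main__":
    main(sys.argv[1], int(sys.argv[2]), int(sys.argv[3]))
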