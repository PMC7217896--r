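>pfam00183_seed1
FDIFCAWHWRYARNGLYPDFTSFDVVCWYGGYGVAMQVHEYLVCKGAVVHIGRNPMVRHVFVYSDYNSLMKHIGCVLCIE
>pfam00183_seed2
FDIGCAEHWRYARDGLCYDFTSFDVVCWENKYVNAMQVHSYAVCKGAVVHIGRNPAVRWVFVYSDYNMLMKHIGCYICIE
>pfam00183_seed3
FDIFCAERWRYARDGLCYDFTSFDIVCWENKYYVAMQVHEYYVCKGAVVHIGRNPMVRWVFVYSYKNSLMKHIGCYICIE
>pfam00183_seed4
FDIFCAEHWRYIRTGLCYGFTSFDVVCWENKYQVAMQVIEYHVCKGAVVHIGRNPMVRWVFVASDYNSLMKAIGCYICIE
>pfam00183_seed5
FDIFCAWHWRYARDKVCYDFTSFDVVCWENKYQVAMQVHKYYVCKGAVVHDGRNPMVRWVFVYSDYNSLMKQIGCYICIE
>pfam00183_seed6
FDIFCAEHWIYAWDGLCYDFTSFDAVCWENKYQVAMQVHDYYVCKGAVVHIGRNPMVRWVFVYSDYNEIMKHIGCYICIE
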