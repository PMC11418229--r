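<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="480.00" height="98.00" viewBox="0 0 480.00 98.00">
<rect x="0" y="0" width="480.00" height="98.00" fill="#ffffff"/>
<text x="390.00" y="22.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="12.00" fill="#000000">a1</text>
<line x1="10.00" y1="58.00" x2="470.00" y2="58.00" stroke="#eeeeee" stroke-width="1"/>
<text x="10.00" y="51.50" font-family="Helvetica, Arial, sans-serif" font-size="12.00" fill="#000000">root process</text>
<line x1="310.00" y1="66.00" x2="470.00" y2="66.00" stroke="#444444" stroke-width="1"/>
<line x1="310.00" y1="66.00" x2="310.00" y2="70.00" stroke="#444444" stroke-width="1"/>
<text x="310.00" y="80.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">0</text>
<line x1="390.00" y1="66.00" x2="390.00" y2="70.00" stroke="#444444" stroke-width="1"/>
<text x="390.00" y="80.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">2.5</text>
<line x1="470.00" y1="66.00" x2="470.00" y2="70.00" stroke="#444444" stroke-width="1"/>
<text x="470.00" y="80.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">5</text>
<text x="390.00" y="92.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">fold change</text>
</svg>
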